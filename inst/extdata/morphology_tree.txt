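# source: Morphologically abnormal structure, neoplasm and hamartoma (synthetic subset)
# Synthetic lexicon: codes follow the axis-letter + 5 digit surface form of
# SNOMED morphology codes but are NOT asserted against any SNOMED release.
M-80000	Neoplasm and hamartoma
  M-80003	Neoplasm malignant
    M-85000	Duct carcinoma
      M-85002	Intraductal carcinoma noninfiltrating
        M-85012	Comedocarcinoma noninfiltrating
        M-85032	Intraductal papillary carcinoma
        M-85072	Intraductal micropapillary carcinoma
      M-85003	Infiltrating duct carcinoma
        M-85013	Comedocarcinoma
        M-85213	Infiltrating ductular carcinoma
        M-85223	Infiltrating duct and lobular carcinoma
    M-85200	Lobular carcinoma
      M-85202	Lobular carcinoma in situ
      M-85203	Lobular carcinoma invasive
    M-84800	Mucinous tumor
      M-84803	Mucinous adenocarcinoma
      M-84813	Mucin producing adenocarcinoma
    M-85400	Paget disease group
      M-85403	Paget disease mammary
      M-85413	Paget disease and infiltrating duct carcinoma
    M-85100	Medullary carcinoma group
      M-85103	Medullary carcinoma
      M-85123	Medullary carcinoma with lymphoid stroma
    M-82110	Tubular neoplasm
      M-82113	Tubular adenocarcinoma
    M-84010	Apocrine neoplasm
      M-84013	Apocrine adenocarcinoma
    M-80220	Pleomorphic neoplasm
      M-80223	Pleomorphic carcinoma
    M-85300	Inflammatory carcinoma group
      M-85303	Inflammatory carcinoma
  M-80001	Neoplasm benign
    M-90100	Fibroadenoma
      M-90110	Intracanalicular fibroadenoma
      M-90120	Pericanalicular fibroadenoma
    M-81400	Adenoma
      M-85030	Intraductal papilloma
      M-85060	Adenoma of nipple
    M-90200	Phyllodes tumor benign
  M-80002	Neoplasm uncertain behavior
    M-90201	Phyllodes tumor borderline
    M-90203	Phyllodes tumor malignant
  M-75500	Hamartoma
    M-75510	Mammary hamartoma
    M-75520	Adenolipoma
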