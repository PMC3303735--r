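<?xml version="1.0" encoding="UTF-8"?>
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema" elementFormDefault="unqualified">
  <xs:simpleType name="percentValue">
    <xs:restriction base="xs:decimal">
      <xs:minInclusive value="0"/>
      <xs:maxInclusive value="100"/>
    </xs:restriction>
  </xs:simpleType>
  <xs:simpleType name="receptorStatus">
    <xs:restriction base="xs:string">
      <xs:enumeration value="positive"/>
      <xs:enumeration value="negative"/>
    </xs:restriction>
  </xs:simpleType>
  <xs:simpleType name="receptorValue">
    <xs:union memberTypes="percentValue receptorStatus"/>
  </xs:simpleType>
  <xs:simpleType name="herScore">
    <xs:restriction base="xs:integer">
      <xs:minInclusive value="0"/>
      <xs:maxInclusive value="3"/>
    </xs:restriction>
  </xs:simpleType>
  <xs:simpleType name="gradeValue">
    <xs:restriction base="xs:integer">
      <xs:minInclusive value="1"/>
      <xs:maxInclusive value="3"/>
    </xs:restriction>
  </xs:simpleType>
  <xs:simpleType name="tnmValue">
    <xs:restriction base="xs:string">
      <xs:pattern value="(yp|p|c)?T(is|1[abc]?|4[abcd]?|[X023]) N(1a?|2a?|[X03]) M[X01]"/>
    </xs:restriction>
  </xs:simpleType>
  <xs:element name="document">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="name" type="xs:string"/>
        <xs:element name="date" type="xs:date"/>
        <xs:element name="type">
          <xs:simpleType>
            <xs:restriction base="xs:string">
              <xs:enumeration value="histological"/>
              <xs:enumeration value="cytological"/>
            </xs:restriction>
          </xs:simpleType>
        </xs:element>
        <xs:element name="number" type="xs:string" minOccurs="0"/>
        <xs:element name="estrogens_receptors" type="receptorValue" minOccurs="0"/>
        <xs:choice minOccurs="0">
          <xs:element name="progesterone_receptors" type="receptorValue"/>
          <xs:element name="progesterone_recoptors" type="receptorValue"/>
        </xs:choice>
        <xs:element name="Ki67" type="percentValue" minOccurs="0"/>
        <xs:element name="c-erb_B2" type="herScore" minOccurs="0"/>
        <xs:element name="grade" type="gradeValue" minOccurs="0"/>
        <xs:element name="state" type="tnmValue" minOccurs="0"/>
        <xs:element name="snomed" minOccurs="0">
          <xs:complexType>
            <xs:sequence minOccurs="0" maxOccurs="unbounded">
              <xs:element name="code" type="xs:string"/>
              <xs:element name="name" type="xs:string"/>
            </xs:sequence>
          </xs:complexType>
        </xs:element>
      </xs:sequence>
    </xs:complexType>
  </xs:element>
</xs:schema>
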