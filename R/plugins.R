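## Analysis plug-ins recast as library functions: Biobank Info (sample rows
## for a patient set and material type, without re-identifying anyone) and
## Kaplan-Meier overall survival (the product-limit estimator, written out
## here because the estimator itself is the deliverable; an established
## survival library serves as an independent cross-check in the test suite,
## never as the implementation).

#' Biobank information for a patient set
#'
#' Returns the sample rows (payload, material, fridge position, consent,
#' meta-attributes) of samples whose donor belongs to the patient set and
#' whose material matches.  Donor resolution goes through the segregated
#' lookup and therefore requires authorization; patient ids themselves are
#' not emitted.
#'
#' @param patient_set a `patient_set` of warehouse patient ids.
#' @param material_type one of the biobank material types, or `NULL` for all.
#' @param biobank biobank store.
#' @param lookup a [new_lookup()].
#' @param authorized access flag for lookup resolution.
#' @return data frame of sample rows (no patient identifiers).
#' @export
biobank_info <- function(patient_set, material_type, biobank, lookup,
                         authorized = FALSE) {
  if (!isTRUE(authorized))
    dw_stop("dw_authorization_error",
            "biobank info requires lookup authorization")
  stopifnot(inherits(patient_set, "patient_set"))
  if (!is.null(material_type) && !material_type %in% MATERIAL_TYPES)
    dw_stop("dw_value_error",
            sprintf("unknown material type '%s'", material_type))
  keep <- logical(nrow(biobank))
  for (i in seq_len(nrow(biobank))) {
    pu <- resolve_payload(lookup, biobank$payload[i], authorized = TRUE)
    ps <- tryCatch(pseudonym_for(lookup, pu, create = FALSE)$warehouse_id,
                   dw_not_found = function(e) NA_character_)
    keep[i] <- !is.na(ps) && ps %in% patient_set$patient_ids &&
      (is.null(material_type) || biobank$material_type[i] == material_type)
  }
  rows <- biobank[keep, , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Kaplan-Meier product-limit survival curve
#'
#' Estimates S(t) = prod over event times t_i <= t of (1 - d_i / n_i),
#' where d_i is the number of deaths at t_i and n_i the number still at
#' risk.  Censored observations at an event time count as at risk for that
#' event (the standard convention).  The median is the first event time at
#' which S falls to 0.5 or below, undefined when the curve never reaches it.
#'
#' @param time non-negative follow-up times (days from the index date).
#' @param event logical (or 0/1): death observed at `time`; `FALSE` means
#'   censored.
#' @param conf also compute Greenwood standard errors.
#' @return a `km_curve`: data frame `time`, `at_risk`, `events`, `survival`
#'   (rows at distinct event times), attributes `n`, `median`.
#' @export
kaplan_meier <- function(time, event, conf = FALSE) {
  if (is.data.frame(time)) {
    event <- time$event
    time <- time$time
  }
  if (!length(time)) dw_stop("dw_value_error", "no survival records")
  if (any(is.na(time)) || any(time < 0))
    dw_stop("dw_validation_error", "survival times must be non-negative")
  event <- as.logical(event)
  times <- sort(unique(time[event]))
  at_risk <- vapply(times, function(t) sum(time >= t), numeric(1))
  events <- vapply(times, function(t) sum(event & time == t), numeric(1))
  surv <- cumprod(1 - events / at_risk)
  curve <- data.frame(time = times, at_risk = at_risk, events = events,
                      survival = surv)
  if (conf && nrow(curve)) {
    gw <- cumsum(events / (at_risk * (at_risk - events)))
    curve$std_err <- surv * sqrt(gw)
  }
  med <- if (any(surv <= 0.5)) times[which(surv <= 0.5)[1]] else NA_real_
  structure(curve, class = c("km_curve", "data.frame"),
            n = length(time), median = med)
}

#' Survival probability at given times
#'
#' @param curve a [kaplan_meier()] curve.
#' @param t times to evaluate at; S(t) is right-continuous and S(0) = 1.
#' @return numeric vector of survival probabilities.
#' @export
km_survival_at <- function(curve, t) {
  vapply(t, function(tt) {
    i <- which(curve$time <= tt)
    if (length(i)) curve$survival[max(i)] else 1
  }, numeric(1))
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, %d event time(s), median = %s\n",
              attr(x, "n"), nrow(x),
              if (is.na(attr(x, "median"))) "undefined"
              else format(attr(x, "median"))))
  print.data.frame(x, ...)
  invisible(x)
}

#' Export a survival curve as delimited text
#'
#' @param curve a `km_curve`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_km_curve <- function(curve, path) {
  dw_write_table(as.data.frame(curve), path)
  invisible(path)
}

#' Plot a survival step curve
#'
#' @param x a `km_curve`.
#' @param ... passed to `plot()`.
#' @export
plot.km_curve <- function(x, ...) {
  tt <- c(0, rep(x$time, each = 2))
  ss <- c(1, 1, rep(x$survival, each = 2)[seq_len(2 * nrow(x) - 1)])
  graphics::plot(tt, ss, type = "l", xlab = "Days from index date",
                 ylab = "Survival probability", ylim = c(0, 1), ...)
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square over the pooled distinct event times.
#'
#' @param time,event survival data as in [kaplan_meier()].
#' @param group two-level grouping vector.
#' @return list with `chisq`, `df`, `p_value`, and per-group observed and
#'   expected event counts.
#' @export
log_rank_test <- function(time, event, group) {
  event <- as.logical(event)
  g <- as.factor(group)
  if (nlevels(g) != 2)
    dw_stop("dw_value_error", "log-rank test requires exactly two groups")
  times <- sort(unique(time[event]))
  obs <- exp_ <- c(0, 0)
  var_sum <- 0
  for (t in times) {
    n <- sum(time >= t)
    d <- sum(event & time == t)
    for (k in 1:2) {
      nk <- sum(time >= t & g == levels(g)[k])
      dk <- sum(event & time == t & g == levels(g)[k])
      obs[k] <- obs[k] + dk
      exp_[k] <- exp_[k] + d * nk / n
    }
    n1 <- sum(time >= t & g == levels(g)[1])
    if (n > 1)
      var_sum <- var_sum + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- if (var_sum > 0) (obs[1] - exp_[1])^2 / var_sum else 0
  list(chisq = chisq, df = 1L,
       p_value = stats::pchisq(chisq, 1, lower.tail = FALSE),
       observed = setNames(obs, levels(g)),
       expected = setNames(exp_, levels(g)))
}

#' Derive overall-survival records from the warehouse
#'
#' Index date: the patient's first diagnosis fact under the SNOMED branch.
#' Deceased patients with a death date are events at death minus index;
#' everyone else is censored at their last visit end date.  Patients with no
#' diagnosis fact, or with a follow-up window that closes before the index
#' date, are excluded.
#'
#' @param warehouse a warehouse.
#' @param concepts concept dimension.
#' @param index_branch concept-path prefix defining the index diagnosis.
#' @return data frame `patient_id`, `time` (days), `event` (logical).
#' @export
survival_records <- function(warehouse, concepts = warehouse$concepts,
                             index_branch = "\\SNOMED\\") {
  codes <- concept_descendants(concepts, index_branch)$concept_code
  f <- warehouse$facts[warehouse$facts$concept_code %in% codes, ,
                       drop = FALSE]
  if (!nrow(f))
    return(data.frame(patient_id = character(0), time = numeric(0),
                      event = logical(0), stringsAsFactors = FALSE))
  idx <- tapply(f$obs_date, f$patient_id, min)
  out <- list()
  for (pid in names(idx)) {
    p <- warehouse$patients[warehouse$patients$patient_id == pid, ]
    index_date <- as.Date(idx[[pid]])
    if (p$vital_status == "deceased" && !is.na(p$death_date)) {
      t <- as.numeric(as.Date(p$death_date) - index_date)
      ev <- TRUE
    } else {
      vis <- warehouse$visits[warehouse$visits$patient_id == pid, ]
      if (!nrow(vis)) next
      t <- as.numeric(max(as.Date(vis$end_date)) - index_date)
      ev <- FALSE
    }
    if (t < 0) next
    out[[length(out) + 1]] <- data.frame(patient_id = pid, time = t,
                                         event = ev, stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(patient_id = character(0), time = numeric(0),
                  event = logical(0), stringsAsFactors = FALSE)
}
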