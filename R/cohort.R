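#' Construct an MMG decompression cohort
#'
#' Bundles a patient-level table (one row per patient: anatomical region and
#' Numeric Pain Scale scores at baseline and six weeks) with a nerve-level
#' table (one row per decompressed nerve root: stimulation thresholds in mA
#' before and after decompression) into a validated cohort object.
#'
#' Validation enforces the structural invariants every downstream metric
#' relies on: unique patient ids, every nerve row joined to exactly one
#' patient, at least one nerve per patient, pain scores in 0--10, and finite
#' positive thresholds. Nerve ordering within a patient is preserved as
#' supplied, because index-nerve selection breaks ties by first occurrence.
#'
#' @param patients data.frame with columns `patient_id`, `region`
#'   (`"lumbar"` or `"cervical"`), `nps_pre`, `nps_6wk` (integers 0--10).
#' @param nerves data.frame with columns `patient_id`, `nerve_label`,
#'   `pre_mA`, `post_mA` (thresholds in milliamperes, >= 1 by protocol;
#'   stored as numeric so externally supplied fractional values load).
#' @param provenance optional list recording source-file names and row counts.
#' @return An object of class `mmg_cohort`: a list with elements `patients`,
#'   `nerves` and `provenance`.
#' @seealso [read_cohort()], [validate_cohort()], [generate_cohort()]
#' @export
#' @examples
#' pts <- data.frame(patient_id = "P1", region = "lumbar",
#'                   nps_pre = 6L, nps_6wk = 0L)
#' nrv <- data.frame(patient_id = "P1", nerve_label = "L5",
#'                   pre_mA = 9, post_mA = 3)
#' coh <- as_cohort(pts, nrv)
#' coh
as_cohort <- function(patients, nerves, provenance = list()) {
  patients <- as.data.frame(patients, stringsAsFactors = FALSE)
  nerves <- as.data.frame(nerves, stringsAsFactors = FALSE)
  req_p <- c("patient_id", "region", "nps_pre", "nps_6wk")
  req_n <- c("patient_id", "nerve_label", "pre_mA", "post_mA")
  miss_p <- setdiff(req_p, names(patients))
  miss_n <- setdiff(req_n, names(nerves))
  if (length(miss_p) || length(miss_n)) {
    stop("schema error: missing required column(s): ",
         paste(c(miss_p, miss_n), collapse = ", "), call. = FALSE)
  }

  patients$patient_id <- as.character(patients$patient_id)
  nerves$patient_id <- as.character(nerves$patient_id)
  patients$region <- as.character(patients$region)

  if (anyDuplicated(patients$patient_id)) {
    stop("duplicate patient_id: ",
         paste(unique(patients$patient_id[duplicated(patients$patient_id)]),
               collapse = ", "), call. = FALSE)
  }
  bad_region <- setdiff(unique(patients$region), c("lumbar", "cervical"))
  if (length(bad_region)) {
    stop("region must be 'lumbar' or 'cervical'; got: ",
         paste(bad_region, collapse = ", "), call. = FALSE)
  }

  for (col in c("nps_pre", "nps_6wk")) {
    v <- patients[[col]]
    if (!is.numeric(v)) {
      stop("parse error: non-numeric ", col, call. = FALSE)
    }
    if (anyNA(v)) {
      dropped <- patients$patient_id[is.na(v)]
      message("dropping ", length(dropped),
              " patient(s) with missing pain data: ",
              paste(dropped, collapse = ", "))
      keep <- !is.na(v)
      patients <- patients[keep, , drop = FALSE]
      nerves <- nerves[nerves$patient_id %in% patients$patient_id, ,
                       drop = FALSE]
      v <- patients[[col]]
    }
    if (any(v < 0 | v > 10)) {
      stop(col, " outside [0, 10] for patient(s): ",
           paste(patients$patient_id[v < 0 | v > 10], collapse = ", "),
           call. = FALSE)
    }
    if (any(v != round(v))) {
      stop(col, " must be an integer score for patient(s): ",
           paste(patients$patient_id[v != round(v)], collapse = ", "),
           call. = FALSE)
    }
    patients[[col]] <- as.integer(v)
  }

  for (col in c("pre_mA", "post_mA")) {
    v <- nerves[[col]]
    if (!is.numeric(v)) {
      stop("parse error: non-numeric ", col, " at row(s) ",
           paste(which(is.na(suppressWarnings(as.numeric(v)))),
                 collapse = ", "), call. = FALSE)
    }
    if (anyNA(v) || any(!is.finite(v))) {
      stop("parse error: missing or non-finite ", col, " at row(s) ",
           paste(which(is.na(v) | !is.finite(v)), collapse = ", "),
           call. = FALSE)
    }
    if (any(v <= 0)) {
      stop(col, " must be positive (stimulation begins at 1 mA); row(s) ",
           paste(which(v <= 0), collapse = ", "), call. = FALSE)
    }
    nerves[[col]] <- as.numeric(v)
  }

  orphans <- setdiff(nerves$patient_id, patients$patient_id)
  if (length(orphans)) {
    stop("join error: nerve rows reference unknown patient_id(s): ",
         paste(sort(unique(orphans)), collapse = ", "), call. = FALSE)
  }
  nerveless <- setdiff(patients$patient_id, nerves$patient_id)
  if (length(nerveless)) {
    stop("join error: patient(s) without any nerve row: ",
         paste(sort(nerveless), collapse = ", "), call. = FALSE)
  }

  rownames(patients) <- NULL
  rownames(nerves) <- NULL
  structure(
    list(patients = patients[, req_p, drop = FALSE],
         nerves = nerves[, req_n, drop = FALSE],
         provenance = provenance),
    class = "mmg_cohort"
  )
}

#' Read a cohort from the two CSV inputs
#'
#' Expects `nerves.csv` (columns `patient_id`, `nerve_label`, `pre_mA`,
#' `post_mA`) and `patients.csv` (columns `patient_id`, `region`, `nps_pre`,
#' `nps_6wk`), comma-separated with a header and `.` decimal. Unknown columns
#' are ignored with a warning; source file names and row counts are recorded
#' in the cohort's provenance.
#'
#' @param nerve_csv,patient_csv paths to the two input files.
#' @return An [as_cohort()] object.
#' @export
read_cohort <- function(nerve_csv, patient_csv) {
  for (f in c(nerve_csv, patient_csv)) {
    if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)
  }
  nerves <- utils::read.csv(nerve_csv, stringsAsFactors = FALSE)
  patients <- utils::read.csv(patient_csv, stringsAsFactors = FALSE)

  extra_n <- setdiff(names(nerves), c("patient_id", "nerve_label", "pre_mA", "post_mA"))
  extra_p <- setdiff(names(patients), c("patient_id", "region", "nps_pre", "nps_6wk"))
  if (length(c(extra_n, extra_p))) {
    warning("ignoring unknown column(s): ",
            paste(c(extra_n, extra_p), collapse = ", "), call. = FALSE)
  }

  as_cohort(patients, nerves,
            provenance = list(nerve_csv = nerve_csv,
                              patient_csv = patient_csv,
                              n_nerve_rows = nrow(nerves),
                              n_patient_rows = nrow(patients)))
}

#' Write a cohort back to CSV
#'
#' Emits the same two schemas [read_cohort()] consumes, so that a write/read
#' round trip reproduces all fields exactly for integer thresholds and pain
#' scores.
#'
#' @param cohort an `mmg_cohort`.
#' @param nerve_csv,patient_csv output paths.
#' @return Invisibly, the cohort.
#' @export
write_cohort <- function(cohort, nerve_csv, patient_csv) {
  stopifnot(inherits(cohort, "mmg_cohort"))
  utils::write.csv(cohort$nerves, nerve_csv, row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$patients, patient_csv, row.names = FALSE, quote = FALSE)
  invisible(cohort)
}

#' Screen a cohort for protocol anomalies
#'
#' Advisory checks that never reject: the stimulation protocol increments in
#' whole milliamperes and produced no threshold worsening in the study cohort,
#' so departures are flagged for review rather than treated as errors.
#'
#' Anomaly kinds:
#' \describe{
#'   \item{worsening}{`post_mA > pre_mA` for a nerve.}
#'   \item{non_integer}{a threshold that is not a whole number of mA.}
#'   \item{zero_baseline}{a patient with baseline NPS = 0 (excluded from all
#'     improvement-fraction analyses downstream).}
#'   \item{implausible}{a threshold above 30 mA.}
#' }
#'
#' @param cohort an `mmg_cohort`.
#' @return data.frame with columns `kind`, `patient_id`, `nerve_label`,
#'   `detail`; zero rows when the cohort is clean.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "mmg_cohort"))
  nv <- cohort$nerves
  pt <- cohort$patients
  out <- list()

  w <- which(nv$post_mA > nv$pre_mA)
  if (length(w)) {
    out[[length(out) + 1L]] <- data.frame(
      kind = "worsening", patient_id = nv$patient_id[w],
      nerve_label = nv$nerve_label[w],
      detail = sprintf("%g -> %g mA", nv$pre_mA[w], nv$post_mA[w]),
      stringsAsFactors = FALSE)
  }
  ni <- which(nv$pre_mA != round(nv$pre_mA) | nv$post_mA != round(nv$post_mA))
  if (length(ni)) {
    out[[length(out) + 1L]] <- data.frame(
      kind = "non_integer", patient_id = nv$patient_id[ni],
      nerve_label = nv$nerve_label[ni],
      detail = sprintf("%g / %g mA", nv$pre_mA[ni], nv$post_mA[ni]),
      stringsAsFactors = FALSE)
  }
  zb <- which(pt$nps_pre == 0)
  if (length(zb)) {
    out[[length(out) + 1L]] <- data.frame(
      kind = "zero_baseline", patient_id = pt$patient_id[zb],
      nerve_label = NA_character_,
      detail = "baseline NPS = 0; excluded from improvement analyses",
      stringsAsFactors = FALSE)
  }
  hi <- which(nv$pre_mA > 30 | nv$post_mA > 30)
  if (length(hi)) {
    out[[length(out) + 1L]] <- data.frame(
      kind = "implausible", patient_id = nv$patient_id[hi],
      nerve_label = nv$nerve_label[hi],
      detail = sprintf("threshold > 30 mA (%g / %g)",
                       nv$pre_mA[hi], nv$post_mA[hi]),
      stringsAsFactors = FALSE)
  }

  if (!length(out)) {
    return(data.frame(kind = character(), patient_id = character(),
                      nerve_label = character(), detail = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Metric configuration
#'
#' Collects the tunable constants of the threshold-anchored analysis.
#'
#' @param reference_mA physiologic reference threshold in mA; currents at or
#'   below it are considered normal nerve function. Default 2.0.
#' @param aggregation how a multi-nerve patient is summarized: `"mean"`
#'   (average across nerves), `"index"` (nerve with the highest
#'   pre-decompression threshold) or `"worst"` (highest post-decompression
#'   threshold).
#' @param mcid_points,mcid_fraction minimal clinically important difference on
#'   the NPS: a reduction of at least `mcid_points` points OR at least
#'   `mcid_fraction` of baseline. Defaults 2 points / 0.30.
#' @param min_improvement_mA minimum threshold drop counted as improvement in
#'   nerve-level summaries. Default 1 mA, the stimulator's increment.
#' @return list of class `mmg_config`.
#' @export
metric_config <- function(reference_mA = 2.0,
                          aggregation = c("mean", "index", "worst"),
                          mcid_points = 2,
                          mcid_fraction = 0.30,
                          min_improvement_mA = 1.0) {
  aggregation <- match.arg(aggregation)
  stopifnot(is.numeric(reference_mA), length(reference_mA) == 1L,
            reference_mA > 0,
            mcid_fraction > 0, mcid_fraction < 1,
            mcid_points >= 0, min_improvement_mA > 0)
  structure(list(reference_mA = reference_mA,
                 aggregation = aggregation,
                 mcid_points = mcid_points,
                 mcid_fraction = mcid_fraction,
                 min_improvement_mA = min_improvement_mA),
            class = "mmg_config")
}

#' @export
print.mmg_cohort <- function(x, ...) {
  cat("MMG decompression cohort: ", nrow(x$patients), " patients, ",
      nrow(x$nerves), " nerves\n", sep = "")
  tab <- table(x$patients$region)
  cat("  regions: ", paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
      "\n", sep = "")
  if (length(x$provenance)) {
    cat("  source: ",
        paste(unlist(x$provenance[c("nerve_csv", "patient_csv")]),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

# nerves of one patient, in stored (read) order
patient_nerves <- function(cohort, id) {
  cohort$nerves[cohort$nerves$patient_id == id, , drop = FALSE]
}
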