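#' Canonical 12-lead order
#'
#' The canonical lead order used throughout the package: limb leads
#' I, II, III, aVR, aVL, aVF followed by precordial leads V1--V6.
#' All waveform matrices are time-major (`L x 12`) with these names as
#' column names.
#'
#' @return Character vector of the 12 canonical lead names.
#' @export
ecg_leads <- function() {
  c("I", "II", "III", "aVR", "aVL", "aVF",
    "V1", "V2", "V3", "V4", "V5", "V6")
}

#' Lead grouping schemes
#'
#' Constructs a lead grouping: a named, ordered partition of the 12
#' canonical leads. Three schemes are supported:
#' \describe{
#'   \item{`none`}{a single group holding all 12 leads;}
#'   \item{`electrical`}{two groups by electrical projection plane:
#'     frontal-plane limb leads (I, II, III, aVR, aVL, aVF) and
#'     horizontal-plane precordial leads (V1--V6);}
#'   \item{`anatomical`}{four groups by supplying coronary territory:
#'     LAD (V1--V4), LCx (I, aVL, V5, V6), RCA (II, III, aVF) and
#'     LM (aVR).}
#' }
#'
#' @param name One of `"none"`, `"electrical"`, `"anatomical"`.
#' @return An object of class `lead_grouping`: a list with `name` and
#'   `groups` (named list of ordered lead-name vectors).
#' @examples
#' lead_grouping("electrical")
#' @export
lead_grouping <- function(name = c("electrical", "none", "anatomical")) {
  name <- match.arg(name)
  groups <- switch(name,
    none = list(all = ecg_leads()),
    electrical = list(
      limb       = c("I", "II", "III", "aVR", "aVL", "aVF"),
      precordial = c("V1", "V2", "V3", "V4", "V5", "V6")
    ),
    anatomical = list(
      LAD = c("V1", "V2", "V3", "V4"),
      LCx = c("I", "aVL", "V5", "V6"),
      RCA = c("II", "III", "aVF"),
      LM  = c("aVR")
    )
  )
  structure(list(name = name, groups = groups), class = "lead_grouping")
}

#' @export
print.lead_grouping <- function(x, ...) {
  cat("Lead grouping:", x$name, "\n")
  for (g in names(x$groups)) {
    cat(sprintf("  %-10s %s\n", g, paste(x$groups[[g]], collapse = ", ")))
  }
  invisible(x)
}

#' Split a waveform into lead-group matrices
#'
#' Slices the columns of a canonical 12-lead waveform matrix (or of the
#' waveform inside an `ecg_record`/`beat_segment`) into the per-group
#' matrices a grouped model consumes. The time axis is untouched and the
#' lead order within each group follows the grouping declaration, not the
#' input order.
#'
#' @param x An `L x 12` matrix with canonical lead column names, or an
#'   `ecg_record`, or a `beat_segment`.
#' @param grouping A [lead_grouping()] object or a scheme name.
#' @return Named list of `L x n_g` matrices, one per group.
#' @export
group_leads <- function(x, grouping = lead_grouping("electrical")) {
  if (is.character(grouping)) grouping <- lead_grouping(grouping)
  if (!inherits(grouping, "lead_grouping")) {
    stop("`grouping` must be a lead_grouping object or a scheme name")
  }
  wf <- if (is.matrix(x)) x else x$waveform
  if (is.null(colnames(wf)) || !setequal(colnames(wf), ecg_leads())) {
    stop("waveform must carry the 12 canonical lead names as column names")
  }
  lapply(grouping$groups, function(leads) wf[, leads, drop = FALSE])
}

# internal: reorder arbitrary lead columns into canonical order, erroring
# on missing/unknown leads (used by the loaders)
canonicalize_leads <- function(wf, record_id = "<record>") {
  want <- ecg_leads()
  have <- colnames(wf)
  if (is.null(have)) stop("record ", record_id, ": leads are unnamed")
  unknown <- setdiff(have, want)
  if (length(unknown)) {
    stop("record ", record_id, ": unknown lead name(s): ",
         paste(unknown, collapse = ", "))
  }
  missing <- setdiff(want, have)
  if (length(missing)) {
    stop("record ", record_id, ": missing lead(s): ",
         paste(missing, collapse = ", "))
  }
  wf[, want, drop = FALSE]
}
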