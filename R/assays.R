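# Closed-form quantitation for the membrane and oxidative-stress assays.
# All operations are exact arithmetic on instrument exports; peak detection
# and spectral correction are out of scope (areas/intensities are inputs).

#' Laurdan membrane-fluidity ratio
#'
#' Computes the pointwise F440/F490 ratio of Laurdan fluorescence emission
#' at 440 nm and 490 nm, the standard relative indicator of membrane
#' fluidity: the probe's emission red-shifts towards ~490 nm in fluid-phase
#' membranes, so a lower ratio indicates a more fluid membrane.
#'
#' @param data Data frame with columns `temperature` (deg C), `f440`,
#'   `f490` (fluorescence intensities), plus any grouping columns (for
#'   example `strain`, `replicate`), which are carried through.
#' @return The input tibble with a `ratio` column (class
#'   `laurdan_series`).
#' @export
laurdan_ratio <- function(data) {
  data <- as_tibble(data)
  req <- c("temperature", "f440", "f490")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols) > 0) {
    stop_format(paste0("laurdan_ratio: missing column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  if (any(data$f490 == 0)) {
    bad <- data$temperature[data$f490 == 0]
    stop_config(paste0("laurdan_ratio: F490 is zero at temperature ",
                       paste(unique(bad), collapse = ", "),
                       " degC; ratio undefined"))
  }
  out <- mutate(data, ratio = .data$f440 / .data$f490)
  structure(out, class = c("laurdan_series", class(out)))
}

#' Acyl-chain percentages from GC peak areas
#'
#' Expresses each fatty-acyl chain as a percentage of the total peak area
#' of the reported chains, excluding the spiked internal standard
#' (C17:1 by default) from the total. When the internal-standard area is
#' supplied, areas scaled to it are also returned
#' (`rel_internal_standard`), but percentages are the primary output.
#'
#' @param areas Named numeric vector of peak areas (names are chain labels
#'   such as `"C18:1"`, `"C18:3n3"`), or a data frame with columns `chain`
#'   and `area`.
#' @param internal_standard_area Optional area of the internal standard.
#' @param internal_standard Chain label of the internal standard, removed
#'   from `areas` if present. Default `"C17:1"`.
#' @return A tibble: `chain`, `area`, `percentage` (sums to 100),
#'   and `rel_internal_standard` when the standard's area was given.
#' @export
acyl_percentages <- function(areas, internal_standard_area = NULL,
                             internal_standard = "C17:1") {
  if (is.data.frame(areas)) {
    tab <- tibble(chain = as.character(areas$chain), area = areas$area)
  } else {
    if (is.null(names(areas))) stop_config("areas must be named by chain")
    tab <- tibble(chain = names(areas), area = unname(areas))
  }
  if (any(tab$area < 0)) stop_config("peak areas must be non-negative")
  if (internal_standard %in% tab$chain) {
    if (is.null(internal_standard_area)) {
      internal_standard_area <- tab$area[tab$chain == internal_standard]
    }
    tab <- filter(tab, .data$chain != internal_standard)
  }
  if (nrow(tab) == 0) stop_config("no chains to report")
  total <- sum(tab$area)
  if (total == 0) stop_config("total peak area is zero")
  out <- mutate(tab, percentage = 100 * .data$area / total)
  if (!is.null(internal_standard_area)) {
    if (internal_standard_area <= 0) {
      stop_config("internal standard area must be positive")
    }
    out <- mutate(out,
                  rel_internal_standard = .data$area / internal_standard_area)
  }
  out
}

#' Normalise a sterol peak to its internal standard
#'
#' @param ergosterol_area Ergosterol peak area.
#' @param internal_standard_area Peak area of the internal standard
#'   (5-alpha-cholestanol).
#' @return The normalised value `ergosterol_area / internal_standard_area`.
#' @export
sterol_normalized <- function(ergosterol_area, internal_standard_area) {
  if (any(internal_standard_area <= 0)) {
    stop_config("internal standard area must be positive")
  }
  if (any(ergosterol_area < 0)) stop_config("ergosterol area must be non-negative")
  ergosterol_area / internal_standard_area
}

#' Ergosterol content relative to a reference strain
#'
#' Compares internal-standard-normalised ergosterol values between a sample
#' and a reference chromatogram; the reference (wild type) is reported as
#' 100%. The result is invariant to rescaling either chromatogram by a
#' common factor, since each is first normalised to its own internal
#' standard.
#'
#' @param sample,reference Normalised sterol values (see
#'   [sterol_normalized()]).
#' @return Percent of reference: `100 * sample / reference`.
#' @export
ergosterol_relative <- function(sample, reference) {
  if (any(reference == 0)) stop_config("reference normalised value is zero")
  100 * sample / reference
}

#' Catalase specific activity in U/mg
#'
#' One unit (U) of catalase decomposes 1 umol of H2O2 per minute; specific
#' activity divides by the protein mass in the assay.
#'
#' @param umol_h2o2 umol of H2O2 decomposed.
#' @param minutes Assay time in minutes.
#' @param protein_mg Protein mass in mg.
#' @return Specific activity in U/mg.
#' @export
catalase_units <- function(umol_h2o2, minutes, protein_mg) {
  if (any(minutes <= 0) || any(protein_mg <= 0) || any(umol_h2o2 < 0)) {
    stop_config("catalase_units: minutes and protein_mg must be positive, umol_h2o2 non-negative")
  }
  (umol_h2o2 / minutes) / protein_mg
}

#' Intracellular ROS relative to a reference, by DCF fluorescence
#'
#' Normalises dichlorofluorescein fluorescence to the protein mass of each
#' sample and reports the sample as a percentage of the reference. The
#' result is invariant to a common fluorometer gain applied to both
#' measurements.
#'
#' @param fluor_sample,fluor_ref Fluorescence intensities (ex 490 / em 524
#'   nm).
#' @param protein_sample,protein_ref Protein masses (mg).
#' @return Percent of reference:
#'   `100 * (fluor_sample / protein_sample) / (fluor_ref / protein_ref)`.
#' @export
ros_relative <- function(fluor_sample, protein_sample, fluor_ref,
                         protein_ref) {
  if (any(c(fluor_sample, protein_sample, fluor_ref, protein_ref) <= 0)) {
    stop_config("ros_relative: all inputs must be positive")
  }
  100 * (fluor_sample / protein_sample) / (fluor_ref / protein_ref)
}

#' Two-sample comparison of replicated assay values
#'
#' Mean +/- SD per group and a two-sample t-test. The default pooled
#' (Student's) variance matches the convention used for these assays;
#' `pooled = FALSE` gives Welch's test.
#'
#' @param values Numeric measurements.
#' @param group Two-level grouping vector.
#' @param pooled Use the pooled-variance (Student's) test. Default `TRUE`.
#' @return A one-row tibble: group means and SDs, `estimate` (difference of
#'   means), `statistic`, `df`, `p_value`.
#' @export
assay_compare <- function(values, group, pooled = TRUE) {
  group <- as.factor(group)
  if (nlevels(group) != 2) stop_config("group must have exactly two levels")
  tt <- t.test(values ~ group, var.equal = pooled)
  lv <- levels(group)
  tibble(
    group1 = lv[1], group2 = lv[2],
    mean1 = mean(values[group == lv[1]]),
    sd1 = sd(values[group == lv[1]]),
    mean2 = mean(values[group == lv[2]]),
    sd2 = sd(values[group == lv[2]]),
    estimate = unname(diff(rev(tt$estimate))),
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value
  )
}
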