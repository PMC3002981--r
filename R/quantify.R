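#' Integrate one MRM peak from a chromatographic trace
#'
#' Deterministic integration contract:
#' \enumerate{
#'   \item the extraction window is `expected_rt +/- rt_tolerance`;
#'   \item the baseline is the median intensity of the outer 10% of the
#'     window (both edges), and the baseline noise estimate is the standard
#'     deviation of those edge points;
#'   \item the apex is the highest point inside the window;
#'   \item integration bounds extend from the apex in both directions until
#'     the signal crosses the baseline or turns upward again (a valley);
#'   \item the area is the trapezoidal integral of `intensity - baseline`
#'     between the bounds, floored at zero;
#'   \item the peak is flagged `not_detected` when the apex rises less than
#'     3x the baseline noise estimate above the baseline (or not at all).
#' }
#'
#' @param trace data.frame with `time` (minutes, strictly increasing) and
#'   `intensity` (counts, non-negative).
#' @param expected_rt expected retention time, minutes.
#' @param rt_tolerance half-width of the extraction window, minutes. The
#'   default 0.5 is half the closest confusable isobaric retention-time gap
#'   (m5C 3.3 min vs m3C 4.4 min).
#' @return A one-row data.frame (`peak_measurement`): `apex_rt`, `area`
#'   (counts x min), `height` (apex minus baseline), `baseline`, `noise`,
#'   and `flags` (semicolon-separated subset of `not_detected`, `rt_shifted`,
#'   `saturated_edge`).
#' @examples
#' tt <- seq(1, 4, by = 0.01)
#' tr <- data.frame(time = tt, intensity = 100 * dnorm(tt, 2.5, 0.05))
#' integrate_peak(tr, expected_rt = 2.5)
#' @export
integrate_peak <- function(trace, expected_rt, rt_tolerance = 0.5) {
  nd <- function(flags = "not_detected") data.frame(
    apex_rt = NA_real_, area = 0, height = 0, baseline = 0, noise = 0,
    flags = flags, stringsAsFactors = FALSE)
  if (is.null(trace) || nrow(trace) == 0) return(nd())
  if (any(diff(trace$time) <= 0))
    stop("trace time axis must be strictly increasing")

  win <- trace[abs(trace$time - expected_rt) <= rt_tolerance, , drop = FALSE]
  if (nrow(win) < 3) return(nd())
  y <- win$intensity
  tt <- win$time
  n <- nrow(win)

  k <- max(1L, floor(0.1 * n))
  edge <- c(y[seq_len(k)], y[seq(n - k + 1L, n)])
  baseline <- stats::median(edge)
  noise <- stats::sd(edge)
  if (is.na(noise)) noise <- 0

  apex <- which.max(y)
  height <- y[apex] - baseline
  flags <- character(0)
  if (height <= 0 || height < 3 * noise) {
    m <- nd()
    m$baseline <- baseline
    m$noise <- noise
    return(m)
  }

  # walk outward from the apex to a baseline crossing or valley
  lo <- apex
  while (lo > 1L && y[lo - 1L] > baseline && y[lo - 1L] <= y[lo]) lo <- lo - 1L
  hi <- apex
  while (hi < n && y[hi + 1L] > baseline && y[hi + 1L] <= y[hi]) hi <- hi + 1L
  if ((lo == 1L || hi == n) && min(y[c(lo, hi)]) > baseline + 3 * noise)
    flags <- c(flags, "saturated_edge")
  if (abs(tt[apex] - expected_rt) > rt_tolerance / 2)
    flags <- c(flags, "rt_shifted")

  yy <- pmax(y[lo:hi] - baseline, 0)
  xx <- tt[lo:hi]
  area <- if (length(xx) > 1)
    sum(diff(xx) * (yy[-length(yy)] + yy[-1]) / 2) else 0
  data.frame(apex_rt = tt[apex], area = max(area, 0), height = height,
             baseline = baseline, noise = noise,
             flags = paste(flags, collapse = ";"), stringsAsFactors = FALSE)
}

has_flag <- function(flags, flag) {
  vapply(strsplit(ifelse(is.na(flags), "", flags), ";", fixed = TRUE),
         function(f) flag %in% f, logical(1))
}

#' Measure every registry transition in one sample
#'
#' Integrates one peak per registry entry from the sample's traces. Isobaric
#' transitions sharing the same m/z pair (m5C vs m3C at 258->126) or parent
#' (the 298-family m7G/Gm/m1G/m2G) are resolved purely chromatographically:
#' each is searched only within `rt_tolerance` of its own scheduled retention
#' time. Tentative analytes carry a `tentative` flag.
#'
#' @param cset a `chromatogram_set`.
#' @param registry an `mrm_registry`.
#' @param rt_tolerance minutes (default 0.5).
#' @param check_is if `TRUE` (default), an undetected or zero-area
#'   internal-standard peak is a hard error, since normalization is then
#'   impossible.
#' @return data.frame of `peak_measurement` rows, one per registry entry,
#'   with `short_name` and `role` prepended.
#' @export
quantify_sample <- function(cset, registry = default_registry(),
                            rt_tolerance = 0.5, check_is = TRUE) {
  stopifnot(inherits(cset, "chromatogram_set"))
  e <- registry$entries
  rows <- lapply(seq_len(nrow(e)), function(i) {
    m <- integrate_peak(cset$traces[[e$short_name[i]]],
                        expected_rt = e$retention_time[i],
                        rt_tolerance = rt_tolerance)
    if (e$role[i] == "tentative_analyte")
      m$flags <- paste(c("tentative", m$flags[m$flags != ""]), collapse = ";")
    cbind(data.frame(short_name = e$short_name[i], role = e$role[i],
                     stringsAsFactors = FALSE), m)
  })
  out <- do.call(rbind, rows)
  if (check_is) {
    is_row <- out[out$role == "internal_standard", ]
    if (has_flag(is_row$flags, "not_detected") || is_row$area <= 0)
      stop("internal-standard peak not detected in sample '", cset$sample_id,
           "': cannot normalize")
  }
  out
}

#' Normalize analyte peak areas to the internal standard and tRNA mass
#'
#' The normalized intensity of an analyte is its peak area divided by the
#' internal-standard peak area and by the tRNA mass hydrolyzed (ug):
#' a dimensionless ratio per microgram tRNA. The ratio cancels per-injection
#' intensity scale; the mass term puts samples of different tRNA input on a
#' common footing. Undetected analytes get value 0 with the flag retained.
#'
#' @param measurements data.frame from [quantify_sample()].
#' @param metadata list with `trna_mass` (ug) and `is_amount` (pmol).
#' @param blank optional named numeric vector of blank areas to subtract from
#'   analyte areas before normalization (floored at 0); off by default.
#' @return Named numeric vector over analytes (internal standard excluded),
#'   with a `flags` attribute carrying per-analyte flag strings.
#' @export
normalize_sample <- function(measurements, metadata, blank = NULL) {
  if (is.null(metadata$trna_mass) || !is.numeric(metadata$trna_mass))
    stop("metadata must supply a numeric trna_mass (ug)")
  if (metadata$trna_mass <= 0) stop("trna_mass must be positive")
  is_row <- measurements[measurements$role == "internal_standard", ]
  if (nrow(is_row) != 1L) stop("expected exactly one internal-standard row")
  if (is_row$area <= 0) stop("internal-standard area is zero: cannot normalize")
  an <- measurements[measurements$role != "internal_standard", ]
  area <- an$area
  if (!is.null(blank)) {
    b <- blank[an$short_name]
    b[is.na(b)] <- 0
    area <- pmax(area - b, 0)
  }
  val <- area / is_row$area / metadata$trna_mass
  val[has_flag(an$flags, "not_detected")] <- 0
  names(val) <- an$short_name
  attr(val, "flags") <- stats::setNames(an$flags, an$short_name)
  val
}

registry_checksum <- function(registry) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(
    apply(registry$entries, 1, paste, collapse = ","), collapse = "\n"), f)
  unname(tools::md5sum(f))
}

#' Build an intensity table from a collection of chromatogram sets
#'
#' Runs [quantify_sample()] and [normalize_sample()] over every sample and
#' assembles the samples x analytes matrix of internal-standard-normalized
#' intensities (the per-experiment quantification product).
#'
#' @param csets list of `chromatogram_set` objects.
#' @param registry an `mrm_registry`.
#' @param rt_tolerance minutes.
#' @param blank optional blank-area vector, see [normalize_sample()].
#' @return An `intensity_table`: data.frame with `sample_id`, `group`, then
#'   one column per analyte. Attributes: `flags` (matrix of flag strings),
#'   `provenance` (normalization mode, rt_tolerance, registry checksum).
#' @export
intensity_table <- function(csets, registry = default_registry(),
                            rt_tolerance = 0.5, blank = NULL) {
  rows <- lapply(csets, function(cs) {
    m <- quantify_sample(cs, registry, rt_tolerance)
    normalize_sample(m, cs$metadata, blank = blank)
  })
  vals <- do.call(rbind, lapply(rows, as.numeric))
  colnames(vals) <- names(rows[[1]])
  out <- data.frame(
    sample_id = vapply(csets, `[[`, character(1), "sample_id"),
    group = vapply(csets, function(cs) cs$metadata$group %||% NA_character_,
                   character(1)),
    vals, check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "flags") <- do.call(rbind, lapply(rows, attr, "flags"))
  attr(out, "provenance") <- list(
    normalization = "area / IS area / tRNA mass (ug)",
    rt_tolerance = rt_tolerance,
    registry_checksum = registry_checksum(registry))
  class(out) <- c("intensity_table", "data.frame")
  out
}

intensity_columns <- function(table) {
  setdiff(colnames(table), c("sample_id", "group"))
}

#' Rank analytes by mean intensity and assign signal tiers
#'
#' Analytes are ranked by mean normalized intensity across samples and binned
#' into high / medium / low signal tiers. Tier boundaries default to decade
#' cuts below the strongest signal: within one decade of the maximum is
#' `high`, within two is `medium`, below that `low`. Ties in the ranking are
#' broken by table (registry) column order. Tiers reflect the product of
#' abundance and mass-spectrometric response, not molar abundance alone.
#'
#' @param table an `intensity_table` (or plain data.frame of the same shape).
#' @param boundaries optional numeric length-2 vector `c(high_min,
#'   medium_min)` of absolute intensity cuts; `NULL` for decade cuts.
#' @return data.frame ranked by descending mean intensity: `short_name`,
#'   `mean_intensity`, `rank`, `tier`.
#' @export
summarize_intensities <- function(table, boundaries = NULL) {
  cols <- intensity_columns(table)
  if (nrow(table) < 1L) stop("intensity table has no samples")
  mu <- vapply(cols, function(cc) mean(table[[cc]]), numeric(1))
  ord <- order(-mu)  # stable: ties keep registry order
  mu <- mu[ord]
  if (is.null(boundaries)) boundaries <- c(max(mu) / 10, max(mu) / 100)
  tier <- ifelse(mu >= boundaries[1], "high",
                 ifelse(mu >= boundaries[2], "medium", "low"))
  data.frame(short_name = names(mu), mean_intensity = unname(mu),
             rank = seq_along(mu), tier = unname(tier),
             stringsAsFactors = FALSE)
}
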