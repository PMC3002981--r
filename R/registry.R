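#' MRM transition registry for yeast cytoplasmic tRNA ribonucleosides
#'
#' A scheduled multiple-reaction-monitoring (MRM) acquisition is driven by a
#' *transition registry*: one (parent m/z, product m/z) pair per analyte,
#' together with its expected retention time, instrument voltages, and the
#' acquisition segment (retention-time window) during which the transition is
#' monitored. `default_registry()` returns the registry used for the 25
#' cytoplasmic tRNA ribonucleoside transitions in *S. cerevisiae*: 23
#' quantified modification analytes, the tentatively identified ncm5Um, and
#' the \[15N5\]-2'-deoxyadenosine internal standard.
#'
#' Product ions are the deglycosylated fragments: loss of ribose (132 u),
#' 2'-O-methylribose (146 u) or deoxyribose (116 u). Pseudouridine (Y) is the
#' exception: its C-C glycosidic bond resists deglycosylation, so it is
#' quantified on a ribose ring fragment (m/z 125, a 120 u loss).
#'
#' Ar(p) (2'-O-ribosyladenosine phosphate) is not detectable in positive ion
#' mode and is excluded by default; it can be added through a custom registry.
#'
#' @param dwell_time Dwell time per transition in seconds (default 0.2).
#'
#' @return An object of class `mrm_registry`: a list with
#'   \describe{
#'     \item{entries}{data.frame, one row per transition: `short_name`,
#'       `long_name`, `retention_time` (min), `parent_mz`, `product_mz`
#'       (integer Th), `fragmentor_voltage`, `collision_energy` (V), `role`
#'       (`"analyte"`, `"internal_standard"` or `"tentative_analyte"`) and
#'       `ribose_class` (`"ribo"`, `"two_prime_O_methyl"`, `"deoxyribo"`,
#'       `"ring_fragment"`).}
#'     \item{segments}{data.frame of acquisition segments: `start_min`,
#'       `end_min`, and `members` (comma-separated short names).}
#'     \item{dwell_time}{seconds per transition per duty cycle.}
#'   }
#' @examples
#' reg <- default_registry()
#' nrow(reg$entries)            # 25 transitions
#' subset(reg$entries, short_name == "D")
#' @export
default_registry <- function(dwell_time = 0.2) {
  e <- read.csv(text = "short_name,long_name,retention_time,parent_mz,product_mz,fragmentor_voltage,collision_energy,role
D,dihydrouridine,1.9,247,115,80,5,analyte
Y,pseudouridine,2.5,245,125,80,10,analyte
m5C,5-methylcytidine,3.3,258,126,80,8,analyte
Cm,2'-O-methylcytidine,3.6,258,112,80,8,analyte
m5U,5-methyluridine,4.2,259,127,80,7,analyte
ncm5U,5-carbamoylmethyluridine,4.3,302,170,90,7,analyte
ac4C,N4-acetylcytidine,4.4,286,154,80,6,analyte
m3C,3-methylcytidine,4.4,258,126,80,8,analyte
Um,2'-O-methyluridine,5.1,259,113,80,7,analyte
m7G,N7-methylguanosine,5.1,298,166,90,10,analyte
ncm5Um,5-carbamoylmethyl-2'-O-methyluridine,5.5,316,170,90,7,tentative_analyte
m1A,N1-methyladenosine,5.7,282,150,100,16,analyte
mcm5U,5-methoxycarbonylmethyluridine,6.4,317,185,90,7,analyte
m1I,N1-methylinosine,7.3,283,151,80,10,analyte
Gm,2'-O-methylguanosine,8.0,298,152,80,7,analyte
m1G,N1-methylguanosine,8.3,298,166,90,10,analyte
m2G,N2-methylguanosine,9.4,298,166,90,10,analyte
I,inosine,10.9,269,137,80,10,analyte
mcm5s2U,5-methoxycarbonylmethyl-2-thiouridine,14.2,333,201,90,7,analyte
15N5-dA,[15N5]-2'-deoxyadenosine,14.4,257,141,90,10,internal_standard
m22G,\"N2,N2-dimethylguanosine\",15.9,312,180,100,8,analyte
t6A,N6-threonylcarbamoyladenosine,17.2,413,281,100,8,analyte
Am,2'-O-methyladenosine,19.0,282,136,100,15,analyte
yW,wybutosine,34.2,509,377,80,5,analyte
i6A,N6-isopentenyladenosine,34.4,336,204,100,17,analyte
", stringsAsFactors = FALSE)
  e$ribose_class <- vapply(seq_len(nrow(e)), function(i)
    mass_shift_class(e$parent_mz[i], e$product_mz[i]), character(1))
  seg <- data.frame(
    start_min = c(1, 4, 7, 10, 30),
    end_min   = c(4, 7, 10, 30, 40),
    members = c(
      "D,Y,m5C,Cm",
      "m5U,ncm5U,ac4C,m3C,ncm5Um,Um,m7G,m1A,mcm5U",
      "m1I,Gm,m1G,m2G",
      "I,mcm5s2U,15N5-dA,m22G,t6A,Am",
      "yW,i6A"),
    stringsAsFactors = FALSE)
  new_registry(e, seg, dwell_time)
}

#' Construct an MRM registry from entries and segments
#'
#' @param entries data.frame with the `TransitionDef` columns (see
#'   [default_registry()]); `ribose_class` is derived from the m/z pair when
#'   absent.
#' @param segments data.frame with `start_min`, `end_min`, `members`.
#' @param dwell_time seconds per transition per duty cycle.
#' @param validate if `TRUE` (default) stop on any invariant violation.
#' @return An `mrm_registry` object.
#' @export
new_registry <- function(entries, segments, dwell_time = 0.2, validate = TRUE) {
  stopifnot(is.data.frame(entries), is.data.frame(segments), dwell_time > 0)
  if (is.null(entries$ribose_class)) {
    entries$ribose_class <- vapply(seq_len(nrow(entries)), function(i)
      mass_shift_class(entries$parent_mz[i], entries$product_mz[i]),
      character(1))
  }
  reg <- structure(
    list(entries = entries, segments = segments, dwell_time = dwell_time),
    class = "mrm_registry")
  if (validate) {
    v <- validate_registry(reg)
    if (length(v))
      stop("invalid registry:\n  ", paste(unlist(v), collapse = "\n  "))
  }
  reg
}

#' @export
print.mrm_registry <- function(x, ...) {
  cat(sprintf("MRM transition registry: %d transitions, %d segments, dwell %g s\n",
              nrow(x$entries), nrow(x$segments), x$dwell_time))
  cat(sprintf("  roles: %s\n",
              paste(names(table(x$entries$role)), table(x$entries$role),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

# expected neutral loss per sugar class (u)
.mass_shift_losses <- c(
  ribo = 132, two_prime_O_methyl = 146, deoxyribo = 116, ring_fragment = 120)

#' Classify a transition by its parent-to-product mass shift
#'
#' The neutral loss from parent to monitored product identifies the sugar:
#' 132 u (ribose) for ordinary ribonucleosides, 146 u for 2'-O-methylated
#' ribonucleosides, 116 u (deoxyribose) for the internal standard, and 120 u
#' for pseudouridine's ribose ring fragment.
#'
#' @param parent_mz,product_mz integer m/z values with `parent_mz > product_mz`.
#' @return One of `"ribo"`, `"two_prime_O_methyl"`, `"deoxyribo"`,
#'   `"ring_fragment"`.
#' @examples
#' mass_shift_class(282, 150)  # "ribo"
#' mass_shift_class(258, 112)  # "two_prime_O_methyl"
#' @export
mass_shift_class <- function(parent_mz, product_mz) {
  if (parent_mz <= product_mz)
    stop("parent_mz (", parent_mz, ") must exceed product_mz (", product_mz, ")")
  loss <- parent_mz - product_mz
  hit <- names(.mass_shift_losses)[.mass_shift_losses == loss]
  if (!length(hit))
    stop("mass shift ", loss, " u for transition ", parent_mz, "->", product_mz,
         " matches no expected sugar loss {132, 146, 116, 120}")
  hit
}

#' Locate the acquisition segment scheduled at a retention time
#'
#' Segments are half-open `[start, end)` except the last, which is closed at
#' the end of the run, so every in-run time maps to exactly one segment.
#'
#' @param registry an `mrm_registry`.
#' @param retention_time minutes.
#' @return Integer segment index (1-based).
#' @examples
#' segment_for(default_registry(), 1.9)   # 1
#' segment_for(default_registry(), 34.4)  # 5
#' @export
segment_for <- function(registry, retention_time) {
  seg <- registry$segments
  n <- nrow(seg)
  for (i in seq_len(n)) {
    upper_ok <- if (i == n) retention_time <= seg$end_min[i]
                else retention_time < seg$end_min[i]
    if (retention_time >= seg$start_min[i] && upper_ok) return(i)
  }
  stop("retention time ", retention_time,
       " min falls in no scheduled acquisition segment")
}

segment_members <- function(registry, i) {
  strsplit(registry$segments$members[i], ",", fixed = TRUE)[[1]]
}

#' Validate a transition registry
#'
#' Checks every structural invariant: retention times within the run, parent
#' above product m/z with a class-consistent neutral loss, unique short names,
#' ordered non-overlapping segments, retention times inside their assigned
#' segments, and exactly one internal-standard entry. Violations are returned
#' as data, not raised.
#'
#' @param registry an `mrm_registry`.
#' @return A list of character violation messages; empty when valid.
#' @examples
#' validate_registry(default_registry())  # list()
#' @export
validate_registry <- function(registry) {
  e <- registry$entries
  seg <- registry$segments
  out <- list()
  bad <- function(...) out[[length(out) + 1L]] <<- sprintf(...)

  dup <- unique(e$short_name[duplicated(e$short_name)])
  for (d in dup) bad("duplicate short_name '%s'", d)

  run_end <- max(seg$end_min)
  for (i in seq_len(nrow(e))) {
    nm <- e$short_name[i]
    if (!(e$retention_time[i] > 0 && e$retention_time[i] <= run_end))
      bad("entry '%s': retention_time %g outside (0, %g]", nm,
          e$retention_time[i], run_end)
    if (e$parent_mz[i] <= e$product_mz[i]) {
      bad("entry '%s': parent_mz %d not above product_mz %d", nm,
          e$parent_mz[i], e$product_mz[i])
    } else {
      loss <- e$parent_mz[i] - e$product_mz[i]
      expected <- .mass_shift_losses[[e$ribose_class[i]]]
      if (is.null(expected) || loss != expected)
        bad("entry '%s': mass shift %d does not match class '%s'", nm, loss,
            e$ribose_class[i])
    }
  }

  if (nrow(seg) > 1) {
    for (i in seq_len(nrow(seg) - 1)) {
      if (seg$end_min[i] > seg$start_min[i + 1])
        bad("segments %d and %d overlap", i, i + 1)
      if (seg$end_min[i] < seg$start_min[i + 1])
        bad("gap between segments %d and %d", i, i + 1)
    }
  }
  for (i in seq_len(nrow(seg)))
    if (seg$start_min[i] >= seg$end_min[i]) bad("segment %d is empty", i)

  # membership/RT consistency
  assigned <- character(0)
  for (i in seq_len(nrow(seg))) {
    for (m in segment_members(registry, i)) {
      assigned <- c(assigned, m)
      j <- match(m, e$short_name)
      if (is.na(j)) { bad("segment %d lists unknown transition '%s'", i, m); next }
      rt <- e$retention_time[j]
      inside <- rt >= seg$start_min[i] &&
        (if (i == nrow(seg)) rt <= seg$end_min[i] else rt < seg$end_min[i])
      if (!inside)
        bad("entry '%s': retention_time %g outside its segment [%g, %g)", m,
            rt, seg$start_min[i], seg$end_min[i])
    }
  }
  for (m in setdiff(e$short_name, assigned))
    bad("entry '%s' assigned to no segment", m)

  n_is <- sum(e$role == "internal_standard")
  if (n_is != 1L)
    bad("registry must contain exactly one internal_standard entry, found %d",
        n_is)
  out
}

#' Internal-standard entry of a registry
#' @param registry an `mrm_registry`.
#' @return Single-row data.frame.
#' @keywords internal
internal_standard <- function(registry) {
  registry$entries[registry$entries$role == "internal_standard", , drop = FALSE]
}

#' Analyte short names of a registry (internal standard excluded)
#' @param registry an `mrm_registry`.
#' @param include_tentative include tentatively identified analytes
#'   (default `TRUE`).
#' @return Character vector in registry order.
#' @export
analyte_names <- function(registry, include_tentative = TRUE) {
  roles <- c("analyte", if (include_tentative) "tentative_analyte")
  registry$entries$short_name[registry$entries$role %in% roles]
}

#' Write / read a registry as a YAML config or CSV
#'
#' The config form is one record per transition plus the segment table and
#' dwell time; it round-trips bit-exactly through [read_registry()]. The CSV
#' form writes the entry table alone.
#'
#' @param registry an `mrm_registry`.
#' @param path file path (`.yml`/`.yaml` for config, `.csv` for table).
#' @return `path`, invisibly (`write_registry`); an `mrm_registry`
#'   (`read_registry`).
#' @export
write_registry <- function(registry, path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    write.csv(registry$entries, path, row.names = FALSE, quote = TRUE)
  } else {
    yaml::write_yaml(list(
      dwell_time = registry$dwell_time,
      segments = lapply(seq_len(nrow(registry$segments)), function(i)
        list(start_min = registry$segments$start_min[i],
             end_min = registry$segments$end_min[i],
             members = segment_members(registry, i))),
      transitions = lapply(seq_len(nrow(registry$entries)), function(i)
        as.list(registry$entries[i, ]))), path)
  }
  invisible(path)
}

#' @rdname write_registry
#' @param segments,dwell_time used when reading the CSV form, which stores the
#'   entry table only; defaults come from [default_registry()].
#' @export
read_registry <- function(path, segments = NULL, dwell_time = NULL) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    e <- read.csv(path, stringsAsFactors = FALSE)
    def <- default_registry()
    new_registry(e,
                 segments = if (is.null(segments)) def$segments else segments,
                 dwell_time = if (is.null(dwell_time)) def$dwell_time else dwell_time)
  } else {
    y <- yaml::read_yaml(path)
    e <- do.call(rbind, lapply(y$transitions, function(tr)
      as.data.frame(tr, stringsAsFactors = FALSE)))
    seg <- data.frame(
      start_min = vapply(y$segments, `[[`, numeric(1), "start_min"),
      end_min = vapply(y$segments, `[[`, numeric(1), "end_min"),
      members = vapply(y$segments, function(s)
        paste(s$members, collapse = ","), character(1)),
      stringsAsFactors = FALSE)
    new_registry(e, seg, y$dwell_time)
  }
}
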