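#' Write / read chromatogram sets in the plain TSV dialect
#'
#' One row per sampled point: `sample_id`, `short_name`, `time_min`,
#' `intensity`. Sample metadata travels in a sidecar CSV (see
#' [write_sample_metadata()]) or is supplied to the reader.
#'
#' @param csets list of `chromatogram_set` objects (or a single one).
#' @param path TSV file path.
#' @return `path` invisibly.
#' @export
write_chromatograms_tsv <- function(csets, path) {
  if (inherits(csets, "chromatogram_set")) csets <- list(csets)
  rows <- lapply(csets, function(cs) {
    do.call(rbind, lapply(names(cs$traces), function(nm) {
      tr <- cs$traces[[nm]]
      if (nrow(tr) == 0) return(NULL)
      data.frame(sample_id = cs$sample_id, short_name = nm,
                 time_min = tr$time, intensity = tr$intensity,
                 stringsAsFactors = FALSE)
    }))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_chromatograms_tsv
#' @param metadata named list of per-sample metadata lists (`trna_mass`,
#'   `is_amount`, `group`), keyed by sample_id; or a data.frame with a
#'   `sample_id` column.
#' @export
read_chromatograms_tsv <- function(path, metadata = NULL) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "short_name", "time_min", "intensity")
  if (!all(need %in% names(d)))
    stop("TSV must have columns: ", paste(need, collapse = ", "))
  if (is.data.frame(metadata)) {
    metadata <- stats::setNames(
      lapply(seq_len(nrow(metadata)), function(i)
        as.list(metadata[i, setdiff(names(metadata), "sample_id")])),
      metadata$sample_id)
  }
  lapply(split(d, d$sample_id), function(ds) {
    traces <- lapply(split(ds, ds$short_name), function(tr) {
      tr <- tr[order(tr$time_min), ]
      data.frame(time = tr$time_min, intensity = tr$intensity)
    })
    structure(list(sample_id = ds$sample_id[1], traces = traces,
                   metadata = metadata[[ds$sample_id[1]]] %||%
                     list(trna_mass = 6, is_amount = 6, group = NA)),
              class = "chromatogram_set")
  })
}

#' Write / read sample metadata CSV
#' @param csets list of `chromatogram_set` objects.
#' @param path CSV path.
#' @return `path` invisibly / data.frame.
#' @export
write_sample_metadata <- function(csets, path) {
  d <- do.call(rbind, lapply(csets, function(cs)
    data.frame(sample_id = cs$sample_id,
               group = cs$metadata$group %||% NA,
               trna_mass = cs$metadata$trna_mass %||% NA,
               is_amount = cs$metadata$is_amount %||% NA,
               stringsAsFactors = FALSE)))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_metadata
#' @export
read_sample_metadata <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)

b64_doubles <- function(x) jsonlite::base64_enc(writeBin(as.double(x), raw(),
                                                         size = 8,
                                                         endian = "little"))
unb64_doubles <- function(s) readBin(jsonlite::base64_dec(s), "double",
                                     n = 1e7, size = 8, endian = "little")

#' Write one chromatogram set as an mzML chromatogram list
#'
#' Produces a minimal chromatogram-list mzML document: one `<chromatogram>`
#' per transition carrying the precursor and product isolation-window m/z,
#' with uncompressed 64-bit little-endian time (minutes) and intensity
#' arrays. [read_chromatograms_mzml()] matches transitions back by
#' precursor/product m/z against a registry and falls back to the
#' chromatogram id.
#'
#' @param cset a `chromatogram_set`.
#' @param path output file path.
#' @param registry registry supplying each transition's m/z pair.
#' @return `path` invisibly.
#' @export
write_chromatograms_mzml <- function(cset, path,
                                     registry = default_registry()) {
  stopifnot(inherits(cset, "chromatogram_set"))
  e <- registry$entries
  doc <- xml2::xml_new_root(
    "mzML", xmlns = "http://psi.hupo.org/ms/mzml", version = "1.1.0")
  run <- xml2::xml_add_child(doc, "run", id = cset$sample_id)
  cl <- xml2::xml_add_child(run, "chromatogramList",
                            count = as.character(length(cset$traces)))
  cv <- function(parent, accession, name, value = NULL, unit = NULL) {
    at <- c(cvRef = "MS", accession = accession, name = name)
    if (!is.null(value)) at <- c(at, value = as.character(value))
    if (!is.null(unit)) at <- c(at, unitName = unit)
    do.call(xml2::xml_add_child, c(list(parent, "cvParam"), as.list(at)))
  }
  idx <- 0L
  for (nm in names(cset$traces)) {
    tr <- cset$traces[[nm]]
    j <- match(nm, e$short_name)
    ch <- xml2::xml_add_child(cl, "chromatogram", index = as.character(idx),
                              id = nm,
                              defaultArrayLength = as.character(nrow(tr)))
    idx <- idx + 1L
    cv(ch, "MS:1001473", "selected reaction monitoring chromatogram")
    if (!is.na(j)) {
      pre <- xml2::xml_add_child(ch, "precursor")
      iw <- xml2::xml_add_child(pre, "isolationWindow")
      cv(iw, "MS:1000827", "isolation window target m/z", e$parent_mz[j])
      prod <- xml2::xml_add_child(ch, "product")
      iw2 <- xml2::xml_add_child(prod, "isolationWindow")
      cv(iw2, "MS:1000827", "isolation window target m/z", e$product_mz[j])
    }
    bal <- xml2::xml_add_child(ch, "binaryDataArrayList", count = "2")
    for (k in 1:2) {
      vals <- if (k == 1) tr$time else tr$intensity
      enc <- b64_doubles(vals)
      ba <- xml2::xml_add_child(bal, "binaryDataArray",
                                encodedLength = as.character(nchar(enc)))
      cv(ba, "MS:1000523", "64-bit float")
      cv(ba, "MS:1000576", "no compression")
      if (k == 1) cv(ba, "MS:1000595", "time array", unit = "minute")
      else cv(ba, "MS:1000515", "intensity array")
      xml2::xml_add_child(ba, "binary", enc)
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname write_chromatograms_mzml
#' @param metadata metadata list for the reconstructed sample.
#' @param sample_id overrides the run id.
#' @export
read_chromatograms_mzml <- function(path, registry = default_registry(),
                                    metadata = list(trna_mass = 6,
                                                    is_amount = 6,
                                                    group = NA),
                                    sample_id = NULL) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  run <- xml2::xml_find_first(doc, ".//run")
  sid <- sample_id %||% xml2::xml_attr(run, "id")
  e <- registry$entries
  chroms <- xml2::xml_find_all(doc, ".//chromatogram")
  traces <- list()
  for (ch in chroms) {
    pre_mz <- as.numeric(xml2::xml_attr(xml2::xml_find_first(
      ch, ".//precursor//cvParam[@accession='MS:1000827']"), "value"))
    prod_mz <- as.numeric(xml2::xml_attr(xml2::xml_find_first(
      ch, ".//product//cvParam[@accession='MS:1000827']"), "value"))
    nm <- NA_character_
    if (!is.na(pre_mz) && !is.na(prod_mz)) {
      j <- which(e$parent_mz == round(pre_mz) & e$product_mz == round(prod_mz))
      if (length(j) == 1) nm <- e$short_name[j]
    }
    if (is.na(nm)) nm <- xml2::xml_attr(ch, "id")   # fallback: id match
    arrays <- xml2::xml_find_all(ch, ".//binaryDataArray")
    tt <- yy <- NULL
    for (ba in arrays) {
      enc <- xml2::xml_text(xml2::xml_find_first(ba, ".//binary"))
      vals <- unb64_doubles(enc)
      if (length(xml2::xml_find_all(ba, ".//cvParam[@accession='MS:1000595']")))
        tt <- vals else yy <- vals
    }
    traces[[nm]] <- data.frame(time = tt, intensity = yy)
  }
  structure(list(sample_id = sid, traces = traces, metadata = metadata),
            class = "chromatogram_set")
}

provenance_header <- function(provenance, seed = NULL) {
  c(sprintf("# trnamrm %s", as.character(utils::packageVersion("trnamrm"))),
    if (!is.null(seed)) sprintf("# seed: %s", seed),
    vapply(names(provenance), function(n)
      sprintf("# %s: %s", n, paste(provenance[[n]], collapse = " ")),
      character(1)))
}

#' Write / read an intensity table as CSV with a provenance header
#'
#' The header is a block of `#`-prefixed lines recording the package
#' version, normalization mode, retention-time tolerance and registry
#' checksum; readers skip it.
#'
#' @param table an `intensity_table`.
#' @param path CSV path.
#' @param seed optional seed recorded in the header.
#' @return `path` invisibly / data.frame.
#' @export
write_intensity_csv <- function(table, path, seed = NULL) {
  prov <- attr(table, "provenance") %||% list()
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(prov, seed), con)
  utils::write.csv(as.data.frame(table), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_intensity_csv
#' @export
read_intensity_csv <- function(path) {
  d <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                       stringsAsFactors = FALSE)
  class(d) <- c("intensity_table", "data.frame")
  d
}

#' Read a fold-change or ratio matrix CSV
#'
#' Conditions (or strains) x analytes, first column the row label, header
#' row of analyte short names — the layout in which published supplementary
#' fold-change and mutant-ratio tables are transcribed.
#'
#' @param path CSV path.
#' @return numeric matrix with dimnames.
#' @export
read_matrix_csv <- function(path) {
  d <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                       stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- d[[1]]
  m
}

#' @rdname read_matrix_csv
#' @param mat numeric matrix with dimnames.
#' @param label name of the first (row-label) column.
#' @export
write_matrix_csv <- function(mat, path, label = "row") {
  d <- data.frame(rownames(mat), as.data.frame(mat), check.names = FALSE)
  names(d)[1] <- label
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Export a cluster tree as merge-history JSON and viewer files
#'
#' `write_cluster_json()` writes the merge history (pair indices, heights,
#' labels). `write_cdt()` writes the tab-delimited clustered-data table plus
#' gene-tree (`.gtr`) file pair consumed by common heat-map viewers, with
#' nodes scored as correlation = 1 - merge height.
#'
#' @param tree a `cluster_tree`.
#' @param path output path (`.json`; for `write_cdt`, the `.cdt` path — the
#'   `.gtr` lands beside it).
#' @return `path` invisibly.
#' @export
write_cluster_json <- function(tree, path) {
  jsonlite::write_json(
    list(labels = tree$labels, merge = tree$merge, height = tree$height,
         order = tree$order, metric = tree$metric, linkage = tree$linkage),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cluster_json
#' @param mat the clustered data matrix (rows = tree leaves).
#' @export
write_cdt <- function(tree, mat, path) {
  stopifnot(identical(rownames(mat), tree$labels))
  n <- length(tree$labels)
  gid <- function(i) sprintf("GENE%dX", i)
  nid <- function(k) sprintf("NODE%dX", k)
  ref <- function(k) if (k < 0) gid(-k) else nid(k)
  gtr <- data.frame(
    node = vapply(seq_len(n - 1), nid, character(1)),
    left = vapply(tree$merge[, 1], ref, character(1)),
    right = vapply(tree$merge[, 2], ref, character(1)),
    correlation = 1 - tree$height)
  utils::write.table(gtr, sub("\\.cdt$", ".gtr", path), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  ord <- tree$order
  cdt <- cbind(GID = vapply(ord, gid, character(1)),
               NAME = tree$labels[ord],
               GWEIGHT = "1",
               format(mat[ord, , drop = FALSE], trim = TRUE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("GID", "NAME", "GWEIGHT", colnames(mat)),
                   collapse = "\t"), con)
  utils::write.table(cdt, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
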