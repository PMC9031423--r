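#' Construct and validate a community table
#'
#' A community table holds non-negative integer OTU counts with samples as
#' rows and OTUs as columns, plus an optional taxonomy map (OTU id to a
#' semicolon-ranked lineage string).
#'
#' @param counts numeric matrix, samples x OTUs; rownames are sample ids and
#'   colnames OTU ids.
#' @param taxonomy optional named character vector mapping OTU ids to lineage
#'   strings such as `"Bacteria; Firmicutes; Bacilli"`.
#' @return an object of class `community_table`.
#' @export
community_table <- function(counts, taxonomy = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have sample ids as rownames and OTU ids as colnames")
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicated sample ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicated OTU ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  }
  if (anyNA(counts) || any(counts < 0)) {
    stop("counts must be non-negative and non-missing")
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be integral")
  }
  counts <- round(counts)
  if (any(rowSums(counts) == 0)) {
    stop("all-zero samples: ",
         paste(rownames(counts)[rowSums(counts) == 0], collapse = ", "))
  }
  if (!is.null(taxonomy)) {
    if (is.null(names(taxonomy))) stop("taxonomy must be named by OTU id")
    taxonomy <- taxonomy[intersect(names(taxonomy), colnames(counts))]
  }
  structure(list(counts = counts, taxonomy = taxonomy),
            class = "community_table")
}

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf("community_table: %d samples x %d OTUs; depth %s-%s%s\n",
              nrow(x$counts), ncol(x$counts), min(rowSums(x$counts)),
              max(rowSums(x$counts)),
              if (is.null(x$taxonomy)) "" else "; taxonomy attached"))
  invisible(x)
}

#' @export
dim.community_table <- function(x) dim(x$counts)

#' Read a community table from TSV or BIOM-JSON
#'
#' The TSV dialect has sample ids in the first column and OTU ids in the
#' header row; `transpose = TRUE` reads the transposed dialect (OTUs as
#' rows). BIOM reading (dense or sparse JSON) is delegated to
#' \pkg{biomformat}; observation metadata, when present, populates the
#' taxonomy map.
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom"`.
#' @param transpose logical; TSV dialect flag.
#' @param taxonomy_path optional TSV (otu_id, lineage) read alongside a TSV
#'   table.
#' @return a [community_table()].
#' @export
read_community_table <- function(path, format = c("tsv", "biom"),
                                 transpose = FALSE, taxonomy_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "biom") {
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")  # OTUs x samples in biom
    taxonomy <- NULL
    om <- tryCatch(biomformat::observation_metadata(b), error = function(e) NULL)
    if (!is.null(om) && length(om)) {
      lineages <- vapply(seq_len(nrow(m)), function(i) {
        x <- if (is.data.frame(om)) unlist(om[i, ]) else unlist(om[[i]])
        paste(x[!is.na(x) & nzchar(x)], collapse = "; ")
      }, character(1))
      taxonomy <- stats::setNames(lineages, rownames(m))
    }
    return(community_table(t(m), taxonomy = taxonomy))
  }
  raw <- tryCatch(
    utils::read.delim(path, check.names = FALSE, row.names = 1),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e)))
  if (nrow(raw) == 0 || ncol(raw) == 0) stop("parse error: empty table in ", path)
  bad <- which(!vapply(raw, is.numeric, logical(1)))
  if (length(bad)) {
    stop("non-numeric counts in column(s): ",
         paste(colnames(raw)[bad], collapse = ", "))
  }
  m <- as.matrix(raw)
  if (transpose) m <- t(m)
  taxonomy <- NULL
  if (!is.null(taxonomy_path)) {
    tx <- utils::read.delim(taxonomy_path, header = TRUE,
                            check.names = FALSE,
                            colClasses = "character")
    taxonomy <- stats::setNames(tx[[2]], tx[[1]])
  }
  community_table(m, taxonomy = taxonomy)
}

#' Write a community table as TSV
#'
#' Inverse of [read_community_table()]'s TSV dialect; counts round-trip
#' exactly.
#'
#' @param table a community_table.
#' @param path output path.
#' @param taxonomy_path optional path for the taxonomy TSV.
#' @export
write_community_table <- function(table, path, taxonomy_path = NULL) {
  stopifnot(inherits(table, "community_table"))
  df <- data.frame(sample_id = rownames(table$counts), table$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(taxonomy_path) && !is.null(table$taxonomy)) {
    utils::write.table(
      data.frame(otu_id = names(table$taxonomy), lineage = table$taxonomy),
      taxonomy_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Rarefy one count vector (internal)
#'
#' Multivariate hypergeometric draw: `depth` reads sampled without
#' replacement from the reads the vector represents.
#' @keywords internal
rarefy_counts <- function(x, depth) {
  total <- sum(x)
  if (depth > total) stop("depth exceeds sample total")
  if (depth == total) return(x)
  reads <- rep.int(seq_along(x), x)
  keep <- sample(reads, depth, replace = FALSE)
  out <- tabulate(keep, nbins = length(x))
  names(out) <- names(x)
  out
}

#' Rarefy a community table to a common depth
#'
#' Each sample is subsampled without replacement (multivariate
#' hypergeometric) to exactly `depth` reads. Deterministic given `seed`.
#'
#' @param table a community_table.
#' @param depth target depth; defaults to the minimum sample total.
#' @param seed integer seed.
#' @param drop_shallow if TRUE, samples with fewer than `depth` reads are
#'   removed with a warning instead of raising an error.
#' @return a rarefied community_table.
#' @export
rarefy <- function(table, depth = min(rowSums(table$counts)), seed = 1L,
                   drop_shallow = FALSE) {
  stopifnot(inherits(table, "community_table"), depth > 0)
  totals <- rowSums(table$counts)
  shallow <- totals < depth
  if (any(shallow)) {
    if (all(shallow)) {
      stop("depth ", depth, " exceeds every sample total; shallow samples: ",
           paste(rownames(table$counts)[shallow], collapse = ", "))
    }
    if (!drop_shallow) {
      stop("samples below depth ", depth, ": ",
           paste(rownames(table$counts)[shallow], collapse = ", "),
           " (use drop_shallow = TRUE to remove them)")
    }
    warning("dropping ", sum(shallow), " sample(s) below depth ", depth, ": ",
            paste(rownames(table$counts)[shallow], collapse = ", "))
  }
  keep <- which(!shallow)
  counts <- table$counts[keep, , drop = FALSE]
  set.seed(seed)
  out <- t(apply(counts, 1, rarefy_counts, depth = depth))
  dimnames(out) <- dimnames(counts)
  community_table(out, taxonomy = table$taxonomy)
}

#' Filter OTUs by prevalence
#'
#' Retains OTUs present (non-zero) in more than `min_fraction` of the
#' samples. The comparison is strict by default (`"gt"`): an OTU must appear
#' in strictly more than `min_fraction * n_samples` samples; `"ge"` is
#' offered for sensitivity checks.
#'
#' @param table a community_table.
#' @param min_fraction prevalence threshold in (0, 1].
#' @param comparison `"gt"` (strict, default) or `"ge"`.
#' @return filtered community_table with attributes `n_retained` and
#'   `retained_share` (per-sample summed relative abundance of the retained
#'   OTUs, computed on the input table).
#' @export
prevalence_filter <- function(table, min_fraction = 0.9,
                              comparison = c("gt", "ge")) {
  stopifnot(inherits(table, "community_table"),
            min_fraction > 0, min_fraction <= 1)
  comparison <- match.arg(comparison)
  n <- nrow(table$counts)
  presence <- colSums(table$counts > 0)
  cutoff <- min_fraction * n
  keep <- if (comparison == "gt") presence > cutoff else presence >= cutoff
  if (!any(keep)) {
    warning("no OTUs pass the prevalence filter (min_fraction = ",
            min_fraction, ")")
  }
  share <- rowSums(table$counts[, keep, drop = FALSE]) / rowSums(table$counts)
  out <- table
  out$counts <- table$counts[, keep, drop = FALSE]
  if (!is.null(table$taxonomy)) {
    out$taxonomy <- table$taxonomy[intersect(names(table$taxonomy),
                                             colnames(out$counts))]
  }
  attr(out, "n_retained") <- sum(keep)
  attr(out, "retained_share") <- share
  out
}

#' Extract the phylum from a lineage string
#' @keywords internal
lineage_phylum <- function(lineage) {
  parts <- trimws(strsplit(lineage, ";", fixed = TRUE)[[1]])
  parts <- sub("^[a-z]__", "", parts)
  parts <- parts[nzchar(parts)]
  if (length(parts) >= 2) parts[2] else NA_character_
}

#' Dominant phyla summary
#'
#' Ranks phyla by mean relative abundance across samples and reports each
#' phylum's min/max relative abundance plus the per-sample coverage of the
#' top `top_k` phyla.
#'
#' @param table a community_table with taxonomy.
#' @param top_k number of phyla to report.
#' @return list with `summary` (data.frame phylum, mean_pct, min_pct,
#'   max_pct) and `coverage` (per-sample summed share of the top phyla, %).
#' @export
phylum_summary <- function(table, top_k = 10) {
  stopifnot(inherits(table, "community_table"))
  if (is.null(table$taxonomy)) stop("taxonomy required for phylum_summary")
  phyla <- vapply(table$taxonomy[colnames(table$counts)], lineage_phylum,
                  character(1))
  phyla[is.na(phyla)] <- "Unclassified"
  ra <- table$counts / rowSums(table$counts)
  by_phylum <- t(rowsum(t(ra), group = phyla))  # samples x phyla
  ord <- order(colMeans(by_phylum), decreasing = TRUE)
  top <- utils::head(ord, top_k)
  summary <- data.frame(
    phylum = colnames(by_phylum)[top],
    mean_pct = 100 * colMeans(by_phylum)[top],
    min_pct = 100 * apply(by_phylum[, top, drop = FALSE], 2, min),
    max_pct = 100 * apply(by_phylum[, top, drop = FALSE], 2, max),
    row.names = NULL)
  coverage <- 100 * rowSums(by_phylum[, top, drop = FALSE])
  list(summary = summary, coverage = coverage)
}

#' Read and validate a sample metadata frame
#'
#' One row per sample with plot, site, treatment (`fresh` / `air_dried`),
#' coordinates in decimal degrees and the measured environmental variables.
#'
#' @param path TSV path.
#' @param require_paired if TRUE, every plot must appear exactly once per
#'   treatment.
#' @return validated data.frame.
#' @export
read_sample_frame <- function(path, require_paired = TRUE) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  validate_sample_frame(df, require_paired = require_paired)
}

#' @rdname read_sample_frame
#' @param frame data.frame to validate in place.
#' @export
validate_sample_frame <- function(frame, require_paired = TRUE) {
  needed <- c("sample_id", "plot_id", "site_id", "treatment",
              "latitude", "longitude")
  missing <- setdiff(needed, colnames(frame))
  if (length(missing)) stop("missing metadata columns: ",
                            paste(missing, collapse = ", "))
  if (anyDuplicated(frame$sample_id)) stop("duplicated sample ids")
  if (!all(frame$treatment %in% c("fresh", "air_dried"))) {
    stop("treatment must be 'fresh' or 'air_dried'")
  }
  if (any(frame$latitude < -90 | frame$latitude > 90)) {
    stop("latitude out of [-90, 90]")
  }
  if (any(frame$longitude < -180 | frame$longitude > 180)) {
    stop("longitude out of [-180, 180]")
  }
  if (require_paired) {
    tab <- table(frame$plot_id, frame$treatment)
    if (!all(tab == 1) || ncol(tab) != 2) {
      stop("paired design violated: every plot needs exactly one fresh and ",
           "one air_dried sample")
    }
  }
  frame
}

#' Default environmental variable set
#'
#' The measured soil physical/chemical variables plus the two climate
#' variables: pH, soil organic carbon (SOC, g/kg), total N/P/K (g/kg),
#' sand/silt/clay (%), water content (WC, %), annual average temperature
#' (AAT, deg C) and annual precipitation (AP, mm).
#' @return character vector of column names.
#' @export
env_variables <- function() {
  c("pH", "SOC", "TN", "TP", "TK", "sand", "silt", "clay", "WC", "AAT", "AP")
}

#' Plot-level metadata
#'
#' Collapses a paired sample frame to one row per plot (coordinates and
#' environmental variables are plot-level properties shared by both
#' treatments).
#' @param frame sample frame.
#' @return data.frame with one row per plot, ordered by plot_id.
#' @export
plot_frame <- function(frame) {
  f <- frame[!duplicated(frame$plot_id), , drop = FALSE]
  f <- f[order(f$plot_id), , drop = FALSE]
  rownames(f) <- f$plot_id
  f
}
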