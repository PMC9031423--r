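#' Labelled distance matrix
#'
#' Thin S3 wrapper around a symmetric zero-diagonal matrix carrying the
#' metric name and units.
#' @param values symmetric numeric matrix with dimnames.
#' @param metric metric name.
#' @param units units string ("" for dissimilarities, "km" for spatial).
#' @return object of class `dist_matrix` (a matrix with attributes).
#' @export
dist_matrix <- function(values, metric = "", units = "") {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (is.null(rownames(values))) stop("dist_matrix needs labels")
  if (max(abs(values - t(values))) > 1e-12) stop("matrix not symmetric")
  if (max(abs(diag(values))) > 1e-12) stop("diagonal not zero")
  values <- (values + t(values)) / 2
  diag(values) <- 0
  structure(values, metric = metric, units = units, class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("dist_matrix (%s%s): %d labels\n", attr(x, "metric"),
              if (nzchar(attr(x, "units"))) paste0(", ", attr(x, "units")) else "",
              nrow(x)))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))])
  invisible(x)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = sum|x_k - y_k| / sum(x_k + y_k)` on the counts as given;
#' rarefaction upstream equalises depth. Computation is delegated to
#' \code{vegan::vegdist}.
#'
#' @param x a community_table or a samples-x-OTUs numeric matrix.
#' @return a `dist_matrix` with entries in [0, 1].
#' @export
bray_curtis <- function(x) {
  m <- if (inherits(x, "community_table")) x$counts else as.matrix(x)
  zero <- rowSums(m) == 0
  if (any(zero)) {
    stop("all-zero sample(s): ", paste(rownames(m)[zero], collapse = ", "))
  }
  d <- as.matrix(vegan::vegdist(m, method = "bray"))
  dimnames(d) <- list(rownames(m), rownames(m))
  dist_matrix(d, metric = "bray_curtis", units = "")
}

#' Great-circle distance matrix between plots
#'
#' Haversine distance on a sphere of mean radius 6371.0088 km; an
#' ellipsoidal (WGS84 geodesic) option is available behind `method`.
#'
#' @param frame plot-level metadata (see [plot_frame()]); needs `plot_id`,
#'   `latitude`, `longitude`.
#' @param method `"haversine"` (default) or `"ellipsoid"`.
#' @return `dist_matrix` in km, one row/column per plot.
#' @export
geodesic_matrix <- function(frame, method = c("haversine", "ellipsoid")) {
  method <- match.arg(method)
  f <- plot_frame(frame)
  bad <- is.na(f$latitude) | is.na(f$longitude)
  if (any(bad)) stop("missing coordinates for plot(s): ",
                     paste(f$plot_id[bad], collapse = ", "))
  p <- as.matrix(f[, c("longitude", "latitude")])
  n <- nrow(p)
  d <- matrix(0, n, n, dimnames = list(f$plot_id, f$plot_id))
  for (i in seq_len(n - 1)) {
    js <- (i + 1):n
    di <- if (method == "haversine") {
      geosphere::distHaversine(p[i, ], p[js, , drop = FALSE], r = 6371008.8)
    } else {
      geosphere::distGeo(p[i, ], p[js, , drop = FALSE])
    }
    d[i, js] <- d[js, i] <- di / 1000
  }
  dist_matrix(d, metric = paste0("great_circle_", method), units = "km")
}

#' Min-max normalise columns to [0, 1]
#' @keywords internal
minmax_scale <- function(m) {
  rng <- apply(m, 2, range)
  span <- rng[2, ] - rng[1, ]
  keep <- span > 0
  if (!any(keep)) stop("all variables constant; cannot normalise")
  if (any(!keep)) {
    warning("dropping constant variable(s): ",
            paste(colnames(m)[!keep], collapse = ", "))
  }
  scale(m[, keep, drop = FALSE], center = rng[1, keep],
        scale = span[keep])
}

#' Environmental difference matrix
#'
#' Each variable is min-max normalised to [0, 1] across the plot set, then
#' plots are compared by Euclidean distance over the normalised vector.
#'
#' @param frame plot-level metadata.
#' @param variables variable names; defaults to [env_variables()].
#' @return `dist_matrix` of environmental differences.
#' @export
environmental_distance <- function(frame, variables = env_variables()) {
  f <- plot_frame(frame)
  missing <- setdiff(variables, colnames(f))
  if (length(missing)) stop("missing environmental variable(s): ",
                            paste(missing, collapse = ", "))
  m <- as.matrix(f[, variables, drop = FALSE])
  storage.mode(m) <- "double"
  z <- minmax_scale(m)
  d <- as.matrix(stats::dist(z, method = "euclidean"))
  dimnames(d) <- list(f$plot_id, f$plot_id)
  dist_matrix(d, metric = "env_minmax_euclidean", units = "")
}

#' Long-form export of a distance matrix
#'
#' @param dm a dist_matrix.
#' @return data.frame (label_a, label_b, value) over unordered pairs,
#'   label_a < label_b.
#' @export
dist_long <- function(dm) {
  labs <- rownames(dm)
  idx <- which(upper.tri(dm), arr.ind = TRUE)
  out <- data.frame(label_a = labs[idx[, 1]], label_b = labs[idx[, 2]],
                    value = dm[idx])
  swap <- out$label_a > out$label_b
  tmp <- out$label_a[swap]
  out$label_a[swap] <- out$label_b[swap]
  out$label_b[swap] <- tmp
  out[order(out$label_a, out$label_b), , drop = FALSE]
}
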