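#' Prepare a raw connectivity matrix for network analysis
#'
#' Symmetrizes by the arithmetic mean of the two directed entries, zeroes the
#' diagonal, and removes the weakest fraction of strictly positive undirected
#' edges (count floored; ties broken deterministically in row-major order).
#' Raw tractography matrices are seed-normalized streamline proportions in
#' \[0, 1\]; entries slightly above 1 (float dust up to `1 + 1e-6`) are clipped
#' with a warning, larger values are an error.
#'
#' @param raw square nonnegative matrix (directed or undirected).
#' @param exclude_bottom_fraction fraction of weakest positive edges to remove
#'   (default 0.10).
#' @param labels region labels (default: dimnames of `raw`).
#' @param provenance subject id or `"group"`.
#' @return object of class `connectome`: list with `adjacency`, `labels`,
#'   `threshold`, `provenance`, `n_edges`.
#' @export
prepare_adjacency <- function(raw, exclude_bottom_fraction = 0.10,
                              labels = NULL, provenance = "subject") {
  stopifnot(is.matrix(raw), nrow(raw) == ncol(raw))
  if (exclude_bottom_fraction < 0 || exclude_bottom_fraction >= 1)
    stop("`exclude_bottom_fraction` must be in [0, 1)", call. = FALSE)
  if (any(raw < 0)) stop("connectivity weights must be nonnegative", call. = FALSE)
  if (any(raw > 1 + 1e-6))
    stop("connectivity weights must be <= 1", call. = FALSE)
  if (any(raw > 1)) {
    warning("clipping weights marginally above 1")
    raw[raw > 1] <- 1
  }
  if (is.null(labels))
    labels <- if (!is.null(rownames(raw))) rownames(raw)
              else sprintf("R%03d", seq_len(nrow(raw)))

  w <- (raw + t(raw)) / 2
  diag(w) <- 0

  ut <- which(upper.tri(w) & w > 0)
  n_remove <- floor(exclude_bottom_fraction * length(ut))
  if (n_remove > 0) {
    # order by weight, then by row-major position for deterministic ties
    ord <- ut[order(w[ut], ut)]
    w[ord[seq_len(n_remove)]] <- 0
    w[lower.tri(w)] <- t(w)[lower.tri(w)]
  }
  dimnames(w) <- list(labels, labels)
  structure(list(adjacency = w, labels = labels,
                 threshold = exclude_bottom_fraction,
                 provenance = provenance,
                 n_edges = sum(w[upper.tri(w)] > 0)),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("Connectome (%s): %d regions, %d edges (bottom %.0f%% removed)\n",
              paste(x$provenance, collapse = ","), length(x$labels),
              x$n_edges, 100 * x$threshold))
  invisible(x)
}

#' All-pairs shortest-path distances on a connectome
#'
#' Edge costs are the reciprocal connectivity weights (`1/w`); zero-weight
#' pairs are non-edges. Distances are computed with Dijkstra's algorithm;
#' unreachable pairs are `Inf` and their count is attached as the attribute
#' `"n_unreachable"`.
#'
#' @param x a `connectome` (or a plain adjacency matrix).
#' @param from optional vector of source region labels or indices; when given,
#'   only those rows of the distance matrix are computed.
#' @return numeric distance matrix (rows = sources).
#' @export
shortest_path_distances <- function(x, from = NULL) {
  w <- if (inherits(x, "connectome")) x$adjacency else x
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE)
  costs <- 1 / igraph::E(g)$weight
  v <- if (is.null(from)) igraph::V(g) else from
  D <- igraph::distances(g, v = v, weights = costs, algorithm = "dijkstra")
  attr(D, "n_unreachable") <- sum(is.infinite(D))
  D
}

#' Group connectome from cognitively unimpaired amyloid-negative subjects
#'
#' Element-wise mean of raw subject matrices over the selected subjects,
#' prepared with the same thresholding policy as the individual connectomes.
#'
#' @param adjacencies named list of raw subject matrices.
#' @param metadata data frame with `subject_id`, `diagnosis`, `abeta_positive`.
#' @param select optional logical vector over `metadata` rows; default selects
#'   `diagnosis == "CU" & !abeta_positive`.
#' @param exclude_bottom_fraction threshold passed to [prepare_adjacency()].
#' @return a `connectome` with provenance `"group"`; the number of averaged
#'   subjects is attached as attribute `"n_averaged"`.
#' @export
group_connectome <- function(adjacencies, metadata, select = NULL,
                             exclude_bottom_fraction = 0.10) {
  if (is.null(select))
    select <- metadata$diagnosis == "CU" & !metadata$abeta_positive
  ids <- metadata$subject_id[select]
  ids <- intersect(ids, names(adjacencies))
  if (length(ids) == 0)
    stop("group-connectome selector matches no subjects", call. = FALSE)
  avg <- Reduce(`+`, adjacencies[ids]) / length(ids)
  out <- prepare_adjacency(avg, exclude_bottom_fraction,
                           provenance = "group")
  attr(out, "n_averaged") <- length(ids)
  out
}

#' Average connectivity distance from epicenters, for all four model variants
#'
#' For each subject and each retained region `r`, computes the mean
#' shortest-path distance from `r` to the members of an epicenter set, under
#' the four crossings of individualized (IE) vs. canonical (GE) epicenters
#' with the individual (IC) vs. group (GC) connectome. A region that is
#' itself an epicenter contributes its zero self-distance to the mean.
#' Infinite (unreachable) distances are dropped from the mean with a warning;
#' a region unreachable from every epicenter gets `NA`. Subjects with an
#' empty epicenter set get `NA` rows in the IE variants.
#'
#' @param subject_adjacencies named list of raw subject matrices.
#' @param epicenter_sets named list of `epicenter_set` objects (one per
#'   subject).
#' @param canonical an `epicenter_set` from [canonical_epicenters()].
#' @param group a group `connectome` from [group_connectome()].
#' @param retained character vector of retained region labels to report.
#' @param exclude_bottom_fraction threshold for individual connectomes.
#' @return list of four subjects-by-retained-regions matrices named
#'   `IE-IC`, `IE-GC`, `GE-IC`, `GE-GC`.
#' @export
epicenter_distance_profiles <- function(subject_adjacencies, epicenter_sets,
                                        canonical, group, retained,
                                        exclude_bottom_fraction = 0.10) {
  ids <- names(epicenter_sets)
  stopifnot(all(ids %in% names(subject_adjacencies)))
  labels <- group$labels
  variants <- c("IE-IC", "IE-GC", "GE-IC", "GE-GC")
  out <- lapply(variants, function(v)
    matrix(NA_real_, length(ids), length(retained),
           dimnames = list(ids, retained)))
  names(out) <- variants

  D_group <- shortest_path_distances(group)
  n_inf <- 0L

  mean_dist <- function(D, eps) {
    sub <- D[eps, retained, drop = FALSE]
    inf <- is.infinite(sub)
    if (any(inf)) { n_inf <<- n_inf + sum(inf); sub[inf] <- NA }
    colMeans(sub, na.rm = TRUE)
  }

  out[["GE-GC"]][] <- matrix(mean_dist(D_group, canonical$regions),
                             length(ids), length(retained), byrow = TRUE)
  ge_gc_row <- out[["GE-GC"]][1, ]

  for (id in ids) {
    eps <- epicenter_sets[[id]]$regions
    conn <- prepare_adjacency(subject_adjacencies[[id]],
                              exclude_bottom_fraction, provenance = id)
    sources <- unique(c(eps, canonical$regions))
    D_ind <- shortest_path_distances(conn, from = sources)
    out[["GE-IC"]][id, ] <- mean_dist(D_ind, canonical$regions)
    if (length(eps) > 0) {
      out[["IE-IC"]][id, ] <- mean_dist(D_ind, eps)
      out[["IE-GC"]][id, ] <- mean_dist(D_group, eps)
    }
  }
  if (n_inf > 0)
    warning(sprintf("%d unreachable epicenter-region pairs dropped from averages", n_inf))
  attr(out, "ge_gc_profile") <- ge_gc_row
  out
}

#' Write an adjacency matrix as a labeled TSV
#'
#' First row and first column carry region labels; cell (i, j) the weight.
#'
#' @param w square matrix with region dimnames.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_connectome_tsv <- function(w, path) {
  df <- data.frame(region = rownames(w), w, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labeled adjacency TSV written by [write_connectome_tsv()]
#'
#' @param path file path.
#' @param expected_labels optional label vector to validate against.
#' @return square numeric matrix with region dimnames.
#' @export
read_connectome_tsv <- function(path, expected_labels = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  labels <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(m) != ncol(m))
    stop("adjacency TSV is not square: ", path, call. = FALSE)
  if (!identical(labels, colnames(m)))
    stop("row and column labels disagree in ", path, call. = FALSE)
  if (!is.null(expected_labels) && !identical(labels, expected_labels))
    stop("region labels in ", path, " do not match the SUVR table",
         call. = FALSE)
  rownames(m) <- labels
  storage.mode(m) <- "double"
  m
}
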