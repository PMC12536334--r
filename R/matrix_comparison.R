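# Cross-matrix occurrence comparison: detection/quantification set algebra,
# per-replicate min-max scaling, PCA and hierarchical clustering of chemical
# profiles, and paired linear correlations between matrices.

#' Detection and quantification sets per matrix
#'
#' A compound counts as *detected* in a matrix if any observation there is
#' `quantified` or `detected_below_loq`, and as *quantified* only on a
#' `quantified` flag — so the quantified set is always a subset of the
#' detected set. Sets are computed per matrix plus `psd_any`, the union over
#' the three sorbent chemistries. Blank matrices are ignored.
#'
#' @param measurements validated measurement tibble.
#' @return object of class `occurrence_sets`: a named list; each element has
#'   `detected` and `quantified` character vectors of compound ids.
#' @export
occurrence_sets <- function(measurements) {
  m <- dplyr::filter(measurements, !.data$matrix %in% BLANK_MATRICES)
  one <- function(df) {
    list(
      detected = sort(unique(df$compound_id[df$censor %in%
        c("quantified", "detected_below_loq")])),
      quantified = sort(unique(df$compound_id[df$censor == "quantified"]))
    )
  }
  present <- intersect(c("water", PSD_MATRICES, "biota"), unique(m$matrix))
  sets <- purrr::map(present, ~ one(dplyr::filter(m, .data$matrix == .x)))
  names(sets) <- present
  for (mx in setdiff(c("water", PSD_MATRICES, "biota"), present)) {
    sets[[mx]] <- list(detected = character(0), quantified = character(0))
  }
  sets$psd_any <- list(
    detected = sort(unique(unlist(purrr::map(sets[PSD_MATRICES], "detected")))),
    quantified = sort(unique(unlist(purrr::map(sets[PSD_MATRICES], "quantified"))))
  )
  structure(sets, class = "occurrence_sets")
}

#' @export
print.occurrence_sets <- function(x, ...) {
  cat("<occurrence_sets>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-12s detected %3d  quantified %3d\n",
                nm, length(x[[nm]]$detected), length(x[[nm]]$quantified)))
  }
  invisible(x)
}

#' Three-set Venn region counts
#'
#' Counts the seven regions of a three-set Venn diagram; region counts sum to
#' the cardinality of the union.
#'
#' @param sets named list of exactly three character vectors.
#' @return tibble with columns `region` (e.g. `"water_only"`,
#'   `"water:psd"`, `"water:psd:biota"`) and `count`.
#' @export
venn_counts <- function(sets) {
  if (length(sets) != 3 || is.null(names(sets))) {
    rlang::abort("sets must be a named list of three sets")
  }
  elems <- unique(unlist(sets, use.names = FALSE))
  member <- matrix(vapply(sets, function(s) elems %in% s,
                          logical(length(elems))),
                   nrow = length(elems), ncol = 3,
                   dimnames = list(NULL, names(sets)))
  nm <- names(sets)
  regions <- list(
    c(TRUE, FALSE, FALSE), c(FALSE, TRUE, FALSE), c(FALSE, FALSE, TRUE),
    c(TRUE, TRUE, FALSE), c(TRUE, FALSE, TRUE), c(FALSE, TRUE, TRUE),
    c(TRUE, TRUE, TRUE)
  )
  label <- function(p) {
    inset <- nm[p]
    if (sum(p) == 1) paste0(inset, "_only") else paste(inset, collapse = ":")
  }
  tibble::tibble(
    region = vapply(regions, label, character(1)),
    count = vapply(regions, function(p) {
      sum(rowSums(member == rep(p, each = nrow(member))) == 3)
    }, numeric(1))
  )
}

#' Wide chemical profile matrix from measurements
#'
#' Builds the replicate-by-compound table used for scaling, PCA and
#' clustering: one row per (matrix, month, replicate), one column per
#' compound, cell values are quantified concentrations/masses in the matrix
#' unit. Censored or absent cells are `NA` at this stage; [minmax_scale()]
#' zero-fills them.
#'
#' @param measurements validated measurement tibble.
#' @return tibble with id columns `matrix`, `month`, `replicate` followed by
#'   one numeric column per compound.
#' @export
profile_matrix <- function(measurements) {
  measurements |>
    dplyr::filter(!.data$matrix %in% BLANK_MATRICES) |>
    dplyr::mutate(value = ifelse(.data$censor == "quantified", .data$value,
                                 NA_real_)) |>
    dplyr::group_by(.data$matrix, .data$month, .data$replicate,
                    .data$compound_id) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "compound_id", values_from = "value")
}

#' Per-replicate min-max scaling to \[0, 1\]
#'
#' Each row (measurement replicate) is scaled independently:
#' `(x - min) / (max - min)` over that row's compounds. Censored/missing
#' entries are zero-filled *before* scaling (non-detects are genuine
#' near-zero occurrence, not missing at random), and constant rows map to
#' all zeros. Scaling is idempotent.
#'
#' @param profiles tibble from [profile_matrix()] (id columns are carried
#'   through untouched) or a bare numeric matrix.
#' @return object of the same shape with numeric entries in \[0, 1\].
#' @export
minmax_scale <- function(profiles) {
  if (is.matrix(profiles)) {
    if (length(profiles) == 0) rlang::abort("empty matrix")
    scaled <- t(apply(profiles, 1, .scale_row))
    dimnames(scaled) <- dimnames(profiles)
    return(scaled)
  }
  num_cols <- names(profiles)[vapply(profiles, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, "replicate")
  if (length(num_cols) == 0 || nrow(profiles) == 0) {
    rlang::abort("no numeric profile columns to scale")
  }
  mat <- as.matrix(profiles[, num_cols])
  scaled <- t(apply(mat, 1, .scale_row))
  out <- profiles
  out[, num_cols] <- tibble::as_tibble(as.data.frame(scaled))
  out
}

.scale_row <- function(x) {
  x[is.na(x)] <- 0
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep(0, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

profile_parts <- function(profiles) {
  id_cols <- intersect(c("matrix", "month", "replicate"), names(profiles))
  list(
    row_info = profiles[, id_cols, drop = FALSE],
    mat = as.matrix(profiles[, setdiff(names(profiles), id_cols), drop = FALSE])
  )
}

#' Principal component analysis of scaled chemical profiles
#'
#' Centred (covariance-based) PCA of the replicate-by-compound matrix. The
#' sign of each component is fixed deterministically by making its
#' largest-magnitude loading positive. Explained variance percentages are
#' non-increasing and sum to 100 over all components.
#'
#' @param profiles scaled profile tibble from [minmax_scale()] (or a numeric
#'   matrix).
#' @param n_components number of components retained for reporting
#'   (default 2, the biplot pair); all components are computed.
#' @param top_k number of compounds reported as top loadings (default 10),
#'   ranked by the largest absolute loading across retained components.
#' @return object of class `profile_pca` with `scores` (tibble, id columns +
#'   `PC1..`), `loadings` (matrix), `explained_var_pct`, `top_loadings`
#'   (character), `n_components`.
#' @export
pca_profiles <- function(profiles, n_components = 2, top_k = 10) {
  parts <- if (is.matrix(profiles)) {
    list(row_info = tibble::tibble(.rows = nrow(profiles)), mat = profiles)
  } else {
    profile_parts(profiles)
  }
  if (nrow(parts$mat) < 2 || ncol(parts$mat) < 2) {
    rlang::abort("PCA needs at least 2 rows and 2 columns")
  }
  pc <- stats::prcomp(parts$mat, center = TRUE, scale. = FALSE)
  # deterministic sign: largest-|loading| entry of each component positive
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  pc$rotation <- sweep(pc$rotation, 2, flip, `*`)
  pc$x <- sweep(pc$x, 2, flip, `*`)
  var_pct <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  k <- min(n_components, ncol(pc$x))
  strength <- apply(abs(pc$rotation[, seq_len(k), drop = FALSE]), 1, max)
  top <- names(sort(strength, decreasing = TRUE))
  top <- top[seq_len(min(top_k, length(top)))]
  scores <- dplyr::bind_cols(parts$row_info,
                             tibble::as_tibble(as.data.frame(pc$x)))
  structure(list(scores = scores, loadings = pc$rotation,
                 explained_var_pct = var_pct, top_loadings = top,
                 n_components = k),
            class = "profile_pca")
}

#' @export
print.profile_pca <- function(x, ...) {
  cat(sprintf("<profile_pca> %d rows, %d components retained\n",
              nrow(x$scores), x$n_components))
  cat("  explained variance (%):",
      paste(sprintf("%.1f", x$explained_var_pct[seq_len(min(4, length(x$explained_var_pct)))]),
            collapse = ", "), "...\n")
  cat("  top loadings:", paste(utils::head(x$top_loadings, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Hierarchical clustering of scaled chemical profiles
#'
#' Agglomerative clustering of replicate rows. Euclidean distance with Ward
#' linkage (`ward.D2`) is the default for min-max-scaled occurrence
#' profiles; both are configurable. The tree is deterministic given the
#' data.
#'
#' @param profiles scaled profile tibble from [minmax_scale()] (or matrix).
#' @param metric distance metric passed to [stats::dist()].
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @param k number of flat clusters to cut (default 2).
#' @return object of class `profile_hca` with the `hclust` tree, `row_info`,
#'   flat `labels` and the call parameters.
#' @export
hca_profiles <- function(profiles, metric = "euclidean", linkage = "ward.D2",
                         k = 2) {
  parts <- if (is.matrix(profiles)) {
    list(row_info = tibble::tibble(.rows = nrow(profiles)), mat = profiles)
  } else {
    profile_parts(profiles)
  }
  if (nrow(parts$mat) < 2) rlang::abort("clustering needs at least 2 rows")
  d <- stats::dist(parts$mat, method = metric)
  tree <- stats::hclust(d, method = linkage)
  structure(list(tree = tree, row_info = parts$row_info,
                 labels = stats::cutree(tree, k = min(k, nrow(parts$mat))),
                 metric = metric, linkage = linkage),
            class = "profile_hca")
}

#' @export
print.profile_hca <- function(x, ...) {
  cat(sprintf("<profile_hca> %d rows, %s distance, %s linkage, %d flat clusters\n",
              length(x$labels), x$metric, x$linkage, length(unique(x$labels))))
  invisible(x)
}

#' Are two rows in the same flat cluster at a cut height?
#'
#' @param hca object from [hca_profiles()].
#' @param i,j row indices.
#' @param h cut height; if `NULL` the stored flat clustering is used.
#' @return logical.
#' @export
same_cluster <- function(hca, i, j, h = NULL) {
  labels <- if (is.null(h)) hca$labels else stats::cutree(hca$tree, h = h)
  labels[i] == labels[j]
}

#' Paired linear correlation between two matrices
#'
#' Ordinary least squares of `y` on `x` for concentration pairs (typically
#' compound x month means from two matrices); the p-value is the slope's
#' t-test.
#'
#' @param x,y numeric vectors of paired values (>= 3 pairs).
#' @return one-row tibble: `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
linear_matrix_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) rlang::abort("at least 3 pairs required")
  fit <- stats::lm(y ~ x)
  s <- suppressWarnings(summary(fit)) # exact linear pairs are legitimate
  tibble::tibble(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = s$r.squared,
    p_value = s$coefficients[2, 4],
    n = length(x)
  )
}

#' Pair per-cell values of two matrices by compound and month
#'
#' Averages quantified replicates per (compound, month) within each matrix
#' and joins the two matrices on compound x month.
#'
#' @param measurements validated measurement tibble.
#' @param matrix_x,matrix_y matrix labels to pair (e.g. `"biota"`,
#'   `"psd_hlb"`).
#' @return tibble with `compound_id`, `month`, `x`, `y`.
#' @export
pair_matrix_values <- function(measurements, matrix_x, matrix_y) {
  cell <- function(mx) {
    measurements |>
      dplyr::filter(.data$matrix == mx, .data$censor == "quantified") |>
      dplyr::group_by(.data$compound_id, .data$month) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop")
  }
  dplyr::inner_join(
    dplyr::rename(cell(matrix_x), x = "value"),
    dplyr::rename(cell(matrix_y), y = "value"),
    by = c("compound_id", "month")
  )
}
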