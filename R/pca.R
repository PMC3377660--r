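#' Default PLFA exclusion list for the community fingerprint
#'
#' Compounds abundant in the diatom substrate itself are excluded from
#' the proportional-uptake fingerprint: 14:0, 16:1(n-7), 16:1(n-5), 16:0
#' and all straight- or iso/anteiso-chain C18 fatty acids. Mid-chain
#' methyl-branched C18s (e.g. 10-Me18:0, a sulfate-reducer marker that
#' discriminates treatments) are retained unless
#' \code{exclude_methyl_c18 = TRUE}.
#'
#' @param names PLFA names to filter.
#' @param exclude_methyl_c18 also exclude mid-chain methyl-branched C18s.
#' @return The subset of \code{names} to exclude.
#' @export
default_plfa_exclusions <- function(names, exclude_methyl_c18 = FALSE) {
  fixed <- c("14:0", "16:1(n-7)", "16:1(n-5)", "16:0")
  c18 <- grepl("^(i|ai|cy)?18:", names)
  if (exclude_methyl_c18) c18 <- c18 | grepl("Me18:", names)
  unique(c(intersect(fixed, names), names[c18]))
}

#' Proportional tracer uptake into individual PLFAs
#'
#' Builds the community-fingerprint matrix: for each core, the tracer
#' carbon of every non-excluded PLFA as a fraction of the core's summed
#' tracer carbon over those compounds. Rows are cores, columns PLFAs;
#' rows sum to one.
#'
#' @param tracer data frame with columns \code{core_id}, \code{plfa},
#'   \code{tracer_mmol_m2} (e.g. assembled from [plfa_tracer_carbon()]
#'   per core).
#' @param exclude PLFA names to drop before renormalizing; defaults to
#'   [default_plfa_exclusions()] applied to the compounds present.
#' @return Numeric matrix (cores x PLFAs) of row-normalized proportions.
#'   Negative propagated tracer values are preserved and flagged with a
#'   warning.
#' @export
proportional_uptake <- function(tracer, exclude = NULL) {
  stopifnot(all(c("core_id", "plfa", "tracer_mmol_m2") %in% names(tracer)))
  if (is.null(exclude)) {
    exclude <- default_plfa_exclusions(unique(tracer$plfa))
  }
  keep <- tracer[!tracer$plfa %in% exclude, ]
  if (!nrow(keep)) stop("exclusion list removed every compound")
  m <- tapply(keep$tracer_mmol_m2, list(keep$core_id, keep$plfa), sum)
  if (anyNA(m)) stop("unbalanced PLFA table: every core needs every included compound")
  rs <- rowSums(m)
  if (any(rs <= 0)) {
    stop("included tracer uptake sums to <= 0 for core(s): ",
         paste(rownames(m)[rs <= 0], collapse = ", "))
  }
  if (any(m < 0)) warning("negative tracer proportions propagated")
  m / rs
}

#' Correlation-based principal components analysis
#'
#' Eigen-decomposition of the correlation matrix of the columns; scores
#' are the column-standardized data projected on the eigenvectors, which
#' preserves inter-row distances of the standardized data (distance
#' biplot: rows in principal coordinates, variables as unit-length
#' loading arrows). For reproducibility each eigenvector is oriented so
#' its largest-magnitude element is positive. Zero-variance columns are
#' dropped with a warning.
#'
#' @param x numeric matrix (rows = samples, columns = variables), e.g.
#'   from [proportional_uptake()].
#' @return Object of class \code{correlation_pca}: \code{eigenvalues},
#'   \code{loadings} (variables x components, orthonormal),
#'   \code{scores} (samples x components), \code{prop_variance}, and
#'   \code{biplot} (list of \code{sites} and \code{arrows} coordinates
#'   for the first two components).
#' @export
correlation_pca <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("at least 2 rows are required")
  v <- apply(x, 2, stats::var)
  if (any(v == 0)) {
    warning("dropping zero-variance column(s): ",
            paste(colnames(x)[v == 0], collapse = ", "))
    x <- x[, v > 0, drop = FALSE]
  }
  if (ncol(x) < 2) stop("at least 2 non-constant columns are required")
  z <- scale(x)
  eg <- eigen(stats::cor(x), symmetric = TRUE)
  flip <- apply(eg$vectors, 2, function(u) sign(u[which.max(abs(u))]))
  load <- sweep(eg$vectors, 2, flip, `*`)
  dimnames(load) <- list(colnames(x), paste0("PC", seq_len(ncol(load))))
  scores <- z %*% load
  ev <- pmax(eg$values, 0)
  structure(list(
    eigenvalues = ev,
    loadings = load,
    scores = scores,
    prop_variance = ev / sum(ev),
    biplot = list(sites = scores[, 1:2, drop = FALSE],
                  arrows = load[, 1:2, drop = FALSE])
  ), class = "correlation_pca")
}

#' @export
print.correlation_pca <- function(x, n = 5, ...) {
  k <- min(n, length(x$eigenvalues))
  cat("Correlation-based PCA:", nrow(x$scores), "samples x",
      nrow(x$loadings), "variables\n")
  tab <- rbind(eigenvalue = x$eigenvalues[1:k],
               `prop. variance` = x$prop_variance[1:k],
               cumulative = cumsum(x$prop_variance)[1:k])
  colnames(tab) <- paste0("PC", 1:k)
  print(round(tab, 4))
  invisible(x)
}
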