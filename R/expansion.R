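# Vertex-wise cortical surface-area expansion between corresponding meshes
# and logistic trajectory maps of expansion versus age.

.check_correspondence <- function(a, b) {
  if (nrow(a$vertices) != nrow(b$vertices) ||
      nrow(a$faces) != nrow(b$faces)) {
    stop("meshes are not in vertex correspondence", call. = FALSE)
  }
}

#' Per-vertex surface-area expansion between two corresponding meshes
#'
#' Forward factor \code{area_i(old) / area_i(young)} and reverse factor (the
#' reciprocal of the old-to-young contraction) are averaged arithmetically;
#' with exact correspondence both directions coincide and the average is the
#' exact ratio. Vertices with zero area on the young mesh are excluded
#' (returned NA) with a warning. Geometric averaging is available for
#' sensitivity analysis.
#'
#' @param young,old Corresponding \code{cortical_mesh} objects (same vertex
#'   count and index correspondence).
#' @param average "arithmetic" (default) or "geometric".
#' @return N-vector of expansion factors.
#' @export
vertex_expansion <- function(young, old, average = c("arithmetic",
                                                     "geometric")) {
  average <- match.arg(average)
  .check_correspondence(young, old)
  a_y <- vertex_areas(young)$vertex_area
  a_o <- vertex_areas(old)$vertex_area
  bad <- a_y <= 0
  if (any(bad)) {
    warning(sum(bad), " vertices with zero young-mesh area excluded",
            call. = FALSE)
  }
  fwd <- ifelse(bad, NA_real_, a_o / a_y)
  rev_contraction <- ifelse(a_o > 0, a_y / a_o, NA_real_)
  rev <- 1 / rev_contraction
  if (average == "arithmetic") (fwd + rev) / 2 else sqrt(fwd * rev)
}

#' Expansion of every age relative to a reference age
#'
#' @param cset Correspondence set as produced by
#'   \code{\link{make_growing_mesh_sequence}}: list with \code{ages} and
#'   \code{meshes} sharing vertex correspondence.
#' @param reference_age Age to expand from; must be one of \code{cset$ages}.
#' @return N x n_ages matrix of expansion factors; the reference column is
#'   exactly 1.
#' @export
expansion_to_reference <- function(cset, reference_age = cset$ages[1]) {
  ref_i <- match(reference_age, cset$ages)
  if (is.na(ref_i)) {
    stop("reference age not in the correspondence set", call. = FALSE)
  }
  ref <- cset$meshes[[ref_i]]
  out <- vapply(seq_along(cset$ages), function(i) {
    if (i == ref_i) rep(1, nrow(ref$vertices))
    else vertex_expansion(ref, cset$meshes[[i]])
  }, numeric(nrow(ref$vertices)))
  colnames(out) <- paste0("age_", cset$ages)
  out
}

#' Vertex-wise logistic expansion trajectories
#'
#' Fits an independent three-parameter logistic curve to each vertex's
#' expansion-versus-age series (expansion relative to the reference age,
#' which enters as exactly 1 at the reference age). Non-converged vertices
#' are masked. Bounds follow the growth-model defaults with the asymptote
#' capped at 50.
#'
#' @param expansion_maps N x n_ages matrix (e.g. from
#'   \code{\link{expansion_to_reference}}).
#' @param ages Ages (days) of the columns, including the adult time point;
#'   at least 4.
#' @return An \code{expansion_trajectory_maps} list: \code{A_map},
#'   \code{Rg_map}, \code{tmid_map}, \code{converged} mask, \code{ages},
#'   and a \code{summary} of parameter percentiles over converged vertices.
#' @export
fit_expansion_trajectories <- function(expansion_maps, ages) {
  stopifnot(ncol(expansion_maps) == length(ages))
  if (length(ages) < 4L) {
    stop("need at least 4 ages for vertex-wise logistic fits",
         call. = FALSE)
  }
  n <- nrow(expansion_maps)
  A_map <- Rg_map <- tmid_map <- rep(NA_real_, n)
  conv <- logical(n)
  for (i in seq_len(n)) {
    y <- expansion_maps[i, ]
    ok <- is.finite(y)
    if (sum(ok) < 4L) next
    fit <- fit_growth_curve("logistic3", ages[ok], pmin(y[ok], 50))
    if (fit$converged) {
      conv[i] <- TRUE
      A_map[i] <- fit$params["A"]
      Rg_map[i] <- fit$params["Rg"]
      tmid_map[i] <- fit$params["tmid"]
    }
  }
  qs <- function(x) stats::quantile(x[conv], c(0.05, 0.25, 0.5, 0.75, 0.95),
                                    na.rm = TRUE)
  structure(list(
    A_map = A_map, Rg_map = Rg_map, tmid_map = tmid_map,
    converged = conv, ages = ages,
    summary = if (any(conv)) rbind(A = qs(A_map), Rg = qs(Rg_map),
                                   tmid = qs(tmid_map)) else NULL
  ), class = "expansion_trajectory_maps")
}

#' @export
print.expansion_trajectory_maps <- function(x, ...) {
  cat(sprintf("Vertex-wise logistic expansion maps: %d vertices, %d converged\n",
              length(x$A_map), sum(x$converged)))
  if (!is.null(x$summary)) print(round(x$summary, 4))
  invisible(x)
}

#' Area-weighted mean expansion difference between two maps
#'
#' Mean of \code{map_b - map_a} weighted by reference-age vertex areas
#' (uniform weights when no reference mesh is supplied).
#'
#' @param map_a,map_b N-vectors of expansion factors.
#' @param reference_mesh Optional reference-age \code{cortical_mesh}
#'   supplying the vertex-area weights.
#' @return Scalar mean difference.
#' @export
mean_expansion_difference <- function(map_a, map_b, reference_mesh = NULL) {
  if (length(map_a) != length(map_b)) {
    stop("expansion maps differ in length", call. = FALSE)
  }
  w <- if (is.null(reference_mesh)) rep(1, length(map_a))
       else vertex_areas(reference_mesh)$vertex_area
  ok <- is.finite(map_a) & is.finite(map_b)
  sum(w[ok] * (map_b[ok] - map_a[ok])) / sum(w[ok])
}
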