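#' Score settlement of final larval positions
#'
#' Tests every non-lost final position against every MPA polygon
#' (point-in-polygon; points on an edge count as inside, ties broken by
#' lowest MPA id) and accumulates the counts matrix: \code{counts[i, j]} is
#' the number of larvae from source MPA j whose final position lies in MPA i.
#' Larvae ending in no MPA are at-large and contribute to no cell.
#'
#' @param traj a \code{\link{trajectory_record}}, or a data.frame with
#'   columns \code{source}, \code{lon}, \code{lat}, \code{status}.
#' @param mpas list of \code{\link{mpa_site}}; ids must be 1..n.
#' @return list with \code{counts} (n x n matrix, destination x source) and
#'   \code{released} (per-source released counts).
#' @export
assign_settlement <- function(traj, mpas) {
  fin <- if (inherits(traj, "trajectory_record")) traj$final else traj
  n <- length(mpas)
  ids <- vapply(mpas, `[[`, integer(1), "id")
  if (!identical(sort(ids), seq_len(n))) {
    stop_domain("MPA ids must be 1..n")
  }
  released <- tabulate(fin$source, nbins = n)
  keep <- fin$status != "lost"
  lonv <- fin$lon[keep]; latv <- fin$lat[keep]; src <- fin$source[keep]
  counts <- matrix(0L, n, n, dimnames = list(ids, ids))
  assigned <- rep(FALSE, length(lonv))
  for (m in order(ids)) {
    mpa <- mpas[[m]]
    todo <- which(!assigned)
    if (!length(todo)) break
    inside <- sp::point.in.polygon(lonv[todo], latv[todo],
                                   mpa$ring[, 1], mpa$ring[, 2]) > 0
    hit <- todo[inside]
    if (length(hit)) {
      tab <- tabulate(src[hit], nbins = n)
      counts[mpa$id, ] <- counts[mpa$id, ] + tab
      assigned[hit] <- TRUE
    }
  }
  list(counts = counts, released = released)
}

#' Connectivity matrix
#'
#' The connection probability \code{c(i, j)} is the fraction of larvae
#' originating in source MPA j that ended up in destination MPA i:
#' \code{c = counts / released}, columnwise. The resolution (detection floor)
#' is \code{1 / max(released)} -- with 50,000 larvae per MPA the smallest
#' detectable probability is 0.00002.
#'
#' @param counts destination-by-source settlement counts
#'   (\code{\link{assign_settlement}}).
#' @param released per-source released counts, all > 0.
#' @return object of class \code{connectivity_matrix} with elements \code{c},
#'   \code{counts}, \code{released}, \code{detection_floor}.
#' @export
connectivity_matrix <- function(counts, released) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  if (ncol(counts) != n) stop_domain("counts must be square")
  released <- rep(released, length.out = n)
  if (any(released <= 0)) stop_domain("released counts must be > 0 for every source")
  if (any(counts < 0) || any(colSums(counts) > released)) {
    stop_domain("settled counts cannot exceed released counts")
  }
  cmat <- sweep(counts, 2, released, `/`)
  if (is.null(rownames(cmat))) {
    dimnames(cmat) <- list(seq_len(n), seq_len(n))
  }
  structure(list(c = cmat, counts = counts, released = released,
                 detection_floor = 1 / max(released)),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf(
    "connectivity_matrix: %d MPAs, connectance %.4f, detection floor %g\n",
    nrow(x$c), connectance(x), x$detection_floor))
  invisible(x)
}

#' Connectance of a connectivity matrix
#'
#' Fraction of connections with nonzero probability: the number of nonzero
#' elements of C divided by its squared size (self-loops included in both
#' numerator and denominator; 115 MPAs give 13,225 possible connections).
#'
#' @param cm a \code{\link{connectivity_matrix}} or plain matrix.
#' @return scalar in [0, 1].
#' @export
connectance <- function(cm) {
  m <- if (inherits(cm, "connectivity_matrix")) cm$c else as.matrix(cm)
  sum(m > 0) / length(m)
}

#' Recruitment statistics per MPA
#'
#' Local retention \code{lr(i) = c(i, i)} (fraction of i's own larvae that
#' settled back in i), self-recruitment
#' \code{sr(i) = c(i, i) / sum_j c(i, j)} (fraction of i's recruits that are
#' locally born), and subsidy recruitment \code{1 - sr(i)}. \code{sr} is
#' \code{NA} (not 0) for MPAs receiving no larvae at all.
#'
#' @param cm a \code{\link{connectivity_matrix}} or plain matrix.
#' @return data.frame with columns \code{mpa}, \code{lr}, \code{sr},
#'   \code{subsidy}, plus the scalar connectance as attribute
#'   \code{"connectance"}.
#' @export
recruitment_stats <- function(cm) {
  m <- if (inherits(cm, "connectivity_matrix")) cm$c else as.matrix(cm)
  n <- nrow(m)
  lr <- diag(m)
  tot_in <- rowSums(m)
  sr <- ifelse(tot_in > 0, lr / tot_in, NA_real_)
  out <- data.frame(mpa = as.integer(rownames(m) %||% seq_len(n)),
                    lr = lr, sr = sr, subsidy = 1 - sr)
  attr(out, "connectance") <- connectance(m)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Larval dispersal distances
#'
#' Great-circle distance (R = 6371 km) from each larva's release point to its
#' final position at the end of the PLD, for non-lost larvae. Summarised per
#' source MPA (mean and max) and pooled (median and quartiles).
#'
#' @param traj a \code{\link{trajectory_record}}.
#' @return list with \code{per_larva} (km, named by particle id),
#'   \code{per_mpa} (data.frame source/mean_km/max_km/n) and \code{pooled}
#'   (named vector: median, q25, q75).
#' @export
dispersal_distances <- function(traj) {
  keep <- traj$final$status != "lost"
  d <- great_circle_km(traj$particles$lon[keep], traj$particles$lat[keep],
                       traj$final$lon[keep], traj$final$lat[keep])
  src <- traj$final$source[keep]
  per_mpa <- do.call(rbind, lapply(split(d, src), function(x) {
    data.frame(mean_km = mean(x), max_km = max(x), n = length(x))
  }))
  per_mpa <- cbind(source = as.integer(rownames(per_mpa)), per_mpa)
  rownames(per_mpa) <- NULL
  q <- stats::quantile(d, c(0.25, 0.5, 0.75), names = FALSE)
  list(per_larva = stats::setNames(d, traj$final$id[keep]),
       per_mpa = per_mpa,
       pooled = c(median = q[2], q25 = q[1], q75 = q[3]))
}

#' Pairwise and nearest-neighbor distances between MPAs
#'
#' Great-circle distances between MPA polygon centroids, the per-MPA
#' nearest-neighbor distance, and summary quantiles of both distributions.
#' Coincident centroids are flagged as degenerate with a warning.
#'
#' @param mpas list of \code{\link{mpa_site}} (at least 2).
#' @return list with \code{pairwise} (n x n km matrix),
#'   \code{nearest_neighbor_km} (named vector) and \code{summary}.
#' @export
mpa_pairwise_distances <- function(mpas) {
  n <- length(mpas)
  if (n < 2) stop_domain("need at least 2 MPAs")
  ctr <- t(vapply(mpas, mpa_centroid, numeric(2)))
  ids <- vapply(mpas, `[[`, integer(1), "id")
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- great_circle_km(ctr[i, 1], ctr[i, 2],
                                          ctr[j, 1], ctr[j, 2])
  }
  off <- d[upper.tri(d)]
  if (any(off == 0)) warning("coincident MPA centroids (degenerate geometry)")
  nn <- apply(d + diag(Inf, n), 1, min)
  list(pairwise = d,
       nearest_neighbor_km = stats::setNames(nn, ids),
       summary = list(
         pairwise = stats::quantile(off, c(0, 0.25, 0.5, 0.75, 1)),
         nearest = stats::quantile(nn, c(0, 0.25, 0.5, 0.75, 1))))
}
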