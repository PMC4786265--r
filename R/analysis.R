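# Native-structure reaction coordinates and thermodynamic observables:
# fraction of native contacts Q, free-energy profiles F(Q), specific heat and
# folding temperature, contact-formation maps, domain centre-of-mass PCA.

.traj_frames <- function(trajectory) {
  if (inherits(trajectory, "sbm_trajectory")) trajectory$frames
  else if (is.array(trajectory) && length(dim(trajectory)) == 3L) trajectory
  else stop("expected an sbm_trajectory or an atoms x 3 x frames array", call. = FALSE)
}

.contact_entries <- function(contacts) {
  if (inherits(contacts, "sbm_contacts")) contacts$entries
  else if (inherits(contacts, "sbm_topology")) contacts$contacts
  else if (is.data.frame(contacts)) contacts
  else stop("expected an sbm_contacts, sbm_topology or data.frame of contacts", call. = FALSE)
}

# per-frame distances for the contact pairs: matrix frames x contacts
.contact_distances <- function(frames, e) {
  nf <- dim(frames)[3]
  out <- matrix(NA_real_, nf, nrow(e))
  for (fr in seq_len(nf)) {
    xyz <- frames[, , fr]
    d <- xyz[e$i, , drop = FALSE] - xyz[e$j, , drop = FALSE]
    out[fr, ] <- sqrt(rowSums(d^2))
  }
  out
}

#' Fraction of native contacts Q per frame
#'
#' A native contact counts as formed in a frame when the pair distance is at
#' most `ratio` times its native distance; Q is the formed fraction. The
#' default ratio is 1.5; 1.2 is a common stricter alternative.
#'
#' @param trajectory an `sbm_trajectory` (or atoms x 3 x frames array).
#' @param contacts an `sbm_contacts`, an `sbm_topology` (its contact table is
#'   used) or a data.frame with columns `i`, `j`, `r0`.
#' @param ratio formation threshold as a multiple of the native distance
#'   (> 1).
#' @return an object of class `sbm_qseries`: list with `q` (per-frame values
#'   in [0, 1]), `ratio`, `n_contacts` and the formation matrix attribute.
#' @export
compute_q <- function(trajectory, contacts, ratio = 1.5) {
  stopifnot(ratio > 1)
  e <- .contact_entries(contacts)
  if (nrow(e) == 0L) stop("empty contact list", call. = FALSE)
  frames <- .traj_frames(trajectory)
  d <- .contact_distances(frames, e)
  formed <- sweep(d, 2, ratio * e$r0, "<=")
  structure(list(q = rowMeans(formed), ratio = ratio, n_contacts = nrow(e),
                 formed = formed),
            class = "sbm_qseries")
}

#' @export
print.sbm_qseries <- function(x, ...) {
  cat(sprintf("Q series: %d frames, %d contacts, ratio %.2f; mean Q = %.3f\n",
              length(x$q), x$n_contacts, x$ratio, mean(x$q)))
  invisible(x)
}

#' Free-energy profile F(Q) = -ln P(Q)
#'
#' Histogram estimate of the free energy along Q in units of k_B T, with the
#' minimum shifted to zero. Defined only on visited bins (NA elsewhere).
#'
#' @param q_series an `sbm_qseries` or numeric vector of Q values.
#' @param n_bins number of bins over [0, 1] (default 40).
#' @return data.frame with `q` (bin centres), `F` (k_B T) and `count`.
#' @export
free_energy_profile <- function(q_series, n_bins = 40L) {
  q <- if (inherits(q_series, "sbm_qseries")) q_series$q else as.numeric(q_series)
  if (!length(q)) stop("empty Q series", call. = FALSE)
  if (length(q) < n_bins) stop("series shorter than the number of bins", call. = FALSE)
  breaks <- seq(0, 1, length.out = n_bins + 1)
  idx <- pmin(pmax(findInterval(q, breaks, rightmost.closed = TRUE), 1L), n_bins)
  count <- tabulate(idx, n_bins)
  Fq <- ifelse(count > 0, -log(count / length(q)), NA_real_)
  Fq <- Fq - min(Fq, na.rm = TRUE)
  data.frame(q = (breaks[-1] + breaks[-length(breaks)]) / 2, F = Fq, count = count)
}

#' Specific heat from energy fluctuations
#'
#' `Cv(T) = (<E^2> - <E>^2) / T^2` with k_B = 1, per temperature. The folding
#' temperature estimate is the peak position refined by quadratic
#' interpolation through the peak and its two neighbours.
#'
#' @param energy_series_by_temperature named list: names are reduced
#'   temperatures, values are (equilibrated) total-energy series.
#' @param equal_area if TRUE, scale the curve to unit area (trapezoidal),
#'   convenient for overlaying models.
#' @return an object of class `sbm_cv`: data.frame with `temperature` and
#'   `cv`, plus attributes `tf` (peak estimate).
#' @export
specific_heat <- function(energy_series_by_temperature, equal_area = FALSE) {
  series <- energy_series_by_temperature
  if (length(series) < 3L) stop("need at least 3 temperatures", call. = FALSE)
  temps <- as.numeric(names(series))
  if (anyNA(temps)) stop("list names must be the temperatures", call. = FALSE)
  ord <- order(temps)
  temps <- temps[ord]; series <- series[ord]
  cv <- vapply(seq_along(series), function(k) {
    e <- as.numeric(series[[k]])
    if (length(e) < 2L) stop("single-frame energy series at T=", temps[k], call. = FALSE)
    mean((e - mean(e))^2) / temps[k]^2
  }, 0)
  if (equal_area && length(temps) > 1) {
    area <- sum(diff(temps) * (cv[-1] + cv[-length(cv)]) / 2)
    if (area > 0) cv <- cv / area
  }
  tf <- .quad_peak(temps, cv)
  out <- data.frame(temperature = temps, cv = cv)
  attr(out, "tf") <- tf
  class(out) <- c("sbm_cv", "data.frame")
  out
}

# quadratic interpolation of the peak position through (x,y) around argmax
.quad_peak <- function(x, y) {
  k <- which.max(y)
  if (k == 1L || k == length(x)) return(x[k])
  xs <- x[(k - 1):(k + 1)]; ys <- y[(k - 1):(k + 1)]
  co <- stats::coef(stats::lm(ys ~ xs + I(xs^2)))
  if (!is.finite(co[3]) || co[3] >= 0) return(x[k])
  xv <- -co[2] / (2 * co[3])
  if (xv < xs[1] || xv > xs[3]) x[k] else as.numeric(xv)
}

#' Per-contact formation probabilities in a Q window
#'
#' For the frames whose Q lies in `q_window`, the frequency with which each
#' native contact is formed (same distance-ratio criterion as [compute_q()]).
#' Use [contact_map_difference()] to compare two maps on a shared contact
#' list.
#'
#' @param trajectory trajectory (or array) the Q series was computed from.
#' @param contacts the contact list used for Q.
#' @param q_series the matching `sbm_qseries`.
#' @param q_window numeric length-2 window on Q (inclusive).
#' @return data.frame `i`, `j`, `probability` plus attribute `n_frames`.
#' @export
contact_formation_map <- function(trajectory, contacts, q_series,
                                  q_window = c(0.25, 0.35)) {
  stopifnot(inherits(q_series, "sbm_qseries"), length(q_window) == 2L)
  e <- .contact_entries(contacts)
  sel <- q_series$q >= q_window[1] & q_series$q <= q_window[2]
  if (!any(sel)) {
    stop(sprintf("no frames with Q in [%g, %g]", q_window[1], q_window[2]), call. = FALSE)
  }
  formed <- q_series$formed
  if (is.null(formed) || ncol(formed) != nrow(e)) {
    frames <- .traj_frames(trajectory)
    d <- .contact_distances(frames, e)
    formed <- sweep(d, 2, q_series$ratio * e$r0, "<=")
  }
  out <- data.frame(i = e$i, j = e$j, probability = colMeans(formed[sel, , drop = FALSE]))
  attr(out, "n_frames") <- sum(sel)
  out
}

#' Difference of two contact-formation maps
#'
#' @param map_a,map_b formation maps from [contact_formation_map()] over the
#'   same contact list.
#' @return data.frame `i`, `j`, `difference` (map_a - map_b).
#' @export
contact_map_difference <- function(map_a, map_b) {
  if (nrow(map_a) != nrow(map_b) ||
      any(map_a$i != map_b$i) || any(map_a$j != map_b$j)) {
    stop("maps must share the same contact list", call. = FALSE)
  }
  data.frame(i = map_a$i, j = map_a$j,
             difference = map_a$probability - map_b$probability)
}

#' PCA of domain centre-of-mass motions
#'
#' Computes the mass-weighted centre of mass of each domain per frame,
#' mean-centres the stacked COM coordinates, and eigendecomposes their
#' covariance. Eigenvalues are in nm^2, sorted descending; their sum equals
#' the total COM-coordinate variance.
#'
#' @param trajectory an `sbm_trajectory` (or array).
#' @param domain_assignments integer vector, one entry per atom, assigning
#'   each atom to a domain (1..n_domains); every domain must be non-empty.
#' @param masses per-atom masses (default 1).
#' @return list with `eigenvalues` (nm^2), `eigenvectors` (columns, over the
#'   stacked per-domain xyz coordinates), `com` (frames x 3*n_domains matrix)
#'   and `n_domains`.
#' @export
compute_com_pca <- function(trajectory, domain_assignments, masses = NULL) {
  frames <- .traj_frames(trajectory)
  n <- dim(frames)[1]; nf <- dim(frames)[3]
  if (nf < 2L) stop("need at least 2 frames for PCA", call. = FALSE)
  dom <- as.integer(domain_assignments)
  if (length(dom) != n) stop("domain_assignments must have one entry per atom", call. = FALSE)
  doms <- sort(unique(dom))
  if (is.null(masses)) masses <- rep(1, n)
  com <- matrix(NA_real_, nf, 3 * length(doms))
  for (k in seq_along(doms)) {
    idx <- which(dom == doms[k])
    if (!length(idx)) stop("empty domain: ", doms[k], call. = FALSE)
    w <- masses[idx] / sum(masses[idx])
    for (fr in seq_len(nf)) {
      com[fr, (3 * k - 2):(3 * k)] <- colSums(frames[idx, , fr, drop = FALSE][, , 1] * w)
    }
  }
  cc <- scale(com, center = TRUE, scale = FALSE)
  cv <- stats::cov(cc)
  eg <- eigen(cv, symmetric = TRUE)
  list(eigenvalues = eg$values, eigenvectors = eg$vectors, com = com,
       n_domains = length(doms))
}

#' Folding temperature from basin populations
#'
#' For each temperature, the F(Q) profile is computed; the reference profile
#' (the one with the highest barrier between its two deepest minima, ties
#' toward lower Q) fixes the barrier-top Q that splits the folded from the
#' unfolded basin. T_F is the temperature where the two basin populations are
#' equal, found by linear interpolation of the folded fraction across
#' temperatures; it should agree with the specific-heat peak for two-state
#' folders.
#'
#' @param q_series_by_temperature named list: names are reduced temperatures,
#'   values are Q series (numeric or `sbm_qseries`).
#' @param n_bins histogram bins for the profiles.
#' @param min_barrier minimal barrier height (k_B T) for a profile to count
#'   as bimodal.
#' @return list with `tf`, `q_split`, `barrier` (k_B T), and `populations`
#'   (data.frame temperature / folded fraction).
#' @export
estimate_tf_from_profiles <- function(q_series_by_temperature, n_bins = 40L,
                                      min_barrier = 0.2) {
  series <- lapply(q_series_by_temperature, function(s) {
    if (inherits(s, "sbm_qseries")) s$q else as.numeric(s)
  })
  temps <- as.numeric(names(series))
  ord <- order(temps); temps <- temps[ord]; series <- series[ord]

  best <- NULL
  for (k in seq_along(series)) {
    prof <- free_energy_profile(series[[k]], n_bins)
    bim <- .profile_bimodality(prof)
    if (!is.null(bim) && (is.null(best) || bim$barrier > best$barrier)) {
      best <- c(bim, list(temperature = temps[k]))
    }
  }
  if (is.null(best) || best$barrier < min_barrier) {
    stop("no temperature shows a bimodal F(Q); cannot locate the transition", call. = FALSE)
  }
  q_split <- best$q_split
  p_fold <- vapply(series, function(q) mean(q > q_split), 0)
  pops <- data.frame(temperature = temps, folded = p_fold)

  cross <- which(diff(sign(p_fold - 0.5)) != 0)
  tf <- if (any(abs(p_fold - 0.5) < 1e-9)) {
    temps[which.min(abs(p_fold - 0.5))]
  } else if (length(cross)) {
    k <- cross[1]
    temps[k] + (0.5 - p_fold[k]) * (temps[k + 1] - temps[k]) / (p_fold[k + 1] - p_fold[k])
  } else {
    stop("temperatures do not bracket the transition (folded fraction never crosses 1/2)",
         call. = FALSE)
  }
  list(tf = unname(tf), q_split = unname(q_split), barrier = unname(best$barrier),
       populations = pops)
}

# two deepest minima of F(Q) and the barrier top between them; NULL if the
# profile has fewer than two local minima
.profile_bimodality <- function(prof) {
  ok <- which(!is.na(prof$F))
  if (length(ok) < 3L) return(NULL)
  q <- prof$q[ok]; Fv <- prof$F[ok]
  n <- length(Fv)
  is_min <- vapply(seq_len(n), function(k) {
    left <- if (k > 1) Fv[k] <= Fv[k - 1] else TRUE
    right <- if (k < n) Fv[k] <= Fv[k + 1] else TRUE
    strict <- (k > 1 && Fv[k] < Fv[k - 1]) || (k < n && Fv[k] < Fv[k + 1])
    left && right && strict
  }, logical(1))
  mins <- which(is_min)
  if (length(mins) < 2L) return(NULL)
  depth_order <- mins[order(Fv[mins])]
  two <- sort(depth_order[1:2])
  between <- two[1]:two[2]
  bar_rel <- which(Fv[between] == max(Fv[between]))[1]  # ties toward lower Q
  bar <- between[bar_rel]
  barrier <- Fv[bar] - max(Fv[two])
  list(q_split = q[bar], barrier = barrier,
       q_minima = q[two], f_minima = Fv[two])
}

#' Write a Q series (TSV)
#' @param q_series an `sbm_qseries`.
#' @param path output file.
#' @export
write_q_tsv <- function(q_series, path) {
  utils::write.table(data.frame(frame = seq_along(q_series$q), q = q_series$q),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a contact-formation map as sparse three-column text
#' @param map formation map from [contact_formation_map()].
#' @param path output file.
#' @export
write_map_tsv <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
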