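# Nonparametric cluster-based randomization inference: element-wise paired t
# maps, adjacency clustering of supra-threshold elements with sum-of-t
# statistics, a max-cluster sign-flip permutation null, and the a-priori ROI
# t tests.

#' Element-wise paired t statistics
#'
#' Classical paired t with df = n_subjects - 1 per element. Elements whose
#' difference has zero variance are flagged (NA) and excluded from
#' clustering.
#'
#' @param a,b subjects x elements matrices for the two conditions, or
#'   \code{a} alone as the difference matrix with \code{b = NULL}.
#' @return numeric vector of t values (NA where flagged), with attribute
#'   \code{flagged} giving the zero-variance element indices.
#' @export
paired_t_map <- function(a, b = NULL) {
  d <- if (is.null(b)) as.matrix(a) else as.matrix(a) - as.matrix(b)
  n <- nrow(d)
  if (n < 2) config_error("paired t map needs >= 2 subjects")
  m <- colMeans(d)
  s2 <- colSums(sweep(d, 2, m)^2) / (n - 1)
  flagged <- which(s2 <= 0)
  t <- m / sqrt(s2 / n)
  t[flagged] <- NA_real_
  attr(t, "flagged") <- flagged
  t
}

# Connected components of `members` (integer element ids) under a neighbor
# list; iterative BFS, returns a list of integer vectors.
graph_components <- function(members, neighbors) {
  if (!length(members)) return(list())
  in_set <- logical(length(neighbors))
  in_set[members] <- TRUE
  seen <- logical(length(neighbors))
  comps <- list()
  for (v in members) {
    if (seen[v]) next
    comp <- integer(0)
    queue <- v
    seen[v] <- TRUE
    while (length(queue)) {
      u <- queue[length(queue)]
      queue <- queue[-length(queue)]
      comp <- c(comp, u)
      nb <- neighbors[[u]]
      nb <- nb[in_set[nb] & !seen[nb]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

#' Form signed supra-threshold clusters
#'
#' Elements with |t| above the critical value of a two-tail test at
#' \code{alpha_two_tail} are partitioned into connected components under the
#' adjacency relation, separately for positive and negative t; each
#' cluster's statistic is the sum of its members' t values.
#'
#' @param t_map numeric t values (NA = excluded).
#' @param adjacency \code{mesh_adjacency} (or anything with \code{neighbors}).
#' @param alpha_two_tail two-tailed cluster-forming alpha (default 0.05).
#' @param df degrees of freedom for the critical value.
#' @param t_crit optional explicit threshold overriding \code{alpha_two_tail}.
#' @return list of clusters, each \code{list(members, sum_t, sign)}; empty
#'   list when nothing is supra-threshold.
#' @export
form_clusters <- function(t_map, adjacency, alpha_two_tail = 0.05, df = NULL,
                          t_crit = NULL) {
  if (is.null(t_crit)) {
    if (is.null(df)) config_error("either df or t_crit must be supplied")
    t_crit <- stats::qt(1 - alpha_two_tail / 2, df)
  }
  out <- list()
  for (sgn in c(1, -1)) {
    members <- which(!is.na(t_map) & sgn * t_map > t_crit)
    for (comp in graph_components(members, adjacency$neighbors)) {
      out[[length(out) + 1L]] <- list(members = comp,
                                      sum_t = sum(t_map[comp]), sign = sgn)
    }
  }
  out
}

#' Lattice adjacency over time-frequency bins
#'
#' Bins are laid out frequency-major (element index = (ti - 1) * n_freq +
#' fi); two bins are adjacent iff they differ by one step in time at the
#' same frequency or one step in frequency at the same time (4-neighborhood,
#' no diagonals).
#'
#' @param frequencies strictly increasing frequency axis.
#' @param times strictly increasing time axis.
#' @return \code{mesh_adjacency} over \code{length(frequencies) *
#'   length(times)} elements, with a \code{dims} attribute.
#' @export
tf_adjacency <- function(frequencies, times) {
  if (is.unsorted(frequencies, strictly = TRUE) || is.unsorted(times, strictly = TRUE))
    config_error("frequency and time axes must be strictly increasing")
  nf <- length(frequencies); nt <- length(times)
  idx <- function(fi, ti) (ti - 1L) * nf + fi
  e1 <- if (nf > 1) cbind(as.vector(outer(seq_len(nf - 1), seq_len(nt), idx)),
                          as.vector(outer(seq_len(nf - 1) + 1L, seq_len(nt), idx)))
  e2 <- if (nt > 1) cbind(as.vector(outer(seq_len(nf), seq_len(nt - 1), idx)),
                          as.vector(outer(seq_len(nf), seq_len(nt - 1) + 1L, idx)))
  adj <- adjacency_from_edges(nf * nt, rbind(e1, e2))
  attr(adj, "dims") <- c(n_freq = nf, n_time = nt)
  adj
}

# Restrict an adjacency structure to a subset of elements, renumbered 1..k.
subset_adjacency <- function(adjacency, keep) {
  keep <- sort(unique(as.integer(keep)))
  map <- integer(adjacency$n)
  map[keep] <- seq_along(keep)
  e <- adjacency$edges
  sel <- map[e[, 1]] > 0 & map[e[, 2]] > 0
  adjacency_from_edges(length(keep), cbind(map[e[sel, 1]], map[e[sel, 2]]))
}

#' Cluster-based sign-flip randomization test for a paired design
#'
#' Observed clusters are formed from the paired t map; the null distribution
#' of the maximum cluster statistic is built by randomly exchanging each
#' subject's condition labels (equivalent to flipping the sign of that
#' subject's difference), recomputing the t map and the maximum |sum-t| over
#' clusters of either sign. Each observed cluster's Monte-Carlo p value is
#' \code{(count of null maxima >= its |sum-t| + 1) / (n_randomizations + 1)};
#' when \code{2^n_subjects <= n_randomizations}, all sign-flip patterns are
#' enumerated exactly (p = count / 2^n, the identity pattern included).
#'
#' @param a,b subjects x elements matrices (condition A, condition B), or
#'   \code{a} the difference matrix with \code{b = NULL}.
#' @param adjacency \code{mesh_adjacency} covering the elements.
#' @param n_randomizations number of label randomizations (default 1500).
#' @param alpha_two_tail cluster-forming two-tail alpha (default 0.05).
#' @param seed integer; results are deterministic given the seed.
#' @return object of class \code{cluster_test_result}: \code{clusters}
#'   (members, sum_t, sign, p), \code{t_map}, \code{threshold_t},
#'   \code{null_distribution}, \code{n_randomizations}, \code{exact},
#'   \code{seed}.
#' @export
permutation_cluster_test <- function(a, b = NULL, adjacency,
                                     n_randomizations = 1500,
                                     alpha_two_tail = 0.05, seed = 1L) {
  d <- if (is.null(b)) as.matrix(a) else as.matrix(a) - as.matrix(b)
  n <- nrow(d); ne <- ncol(d)
  if (n < 2) config_error("cluster test needs >= 2 subjects")
  if (adjacency$n != ne)
    data_error("adjacency covers %d elements but data has %d", adjacency$n, ne)
  if (n_randomizations < 100)
    warning("fewer than 100 randomizations: p values will be coarse")
  t_obs <- paired_t_map(d)
  df <- n - 1
  t_crit <- stats::qt(1 - alpha_two_tail / 2, df)
  clusters <- form_clusters(t_obs, adjacency, df = df, t_crit = t_crit)

  exact <- 2^n <= n_randomizations
  if (exact) {
    n_perm <- 2^n
    signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  } else {
    n_perm <- n_randomizations
    signs <- with_seed(seed,
                       matrix(sample(c(1, -1), n_perm * n, replace = TRUE), n_perm, n))
  }
  ok <- which(!is.na(t_obs))
  SS <- colSums(d^2)[ok]
  Dok <- d[, ok, drop = FALSE]
  M <- (signs %*% Dok) / n
  V <- (matrix(SS, n_perm, length(ok), byrow = TRUE) - n * M^2) / (n - 1)
  V[V < 0] <- 0
  Tperm <- M / sqrt(V / n)
  null_max <- numeric(n_perm)
  nb_ok <- subset_adjacency(adjacency, ok)$neighbors
  for (p_ in seq_len(n_perm)) {
    tp <- Tperm[p_, ]
    best <- 0
    for (sgn in c(1, -1)) {
      members <- which(is.finite(tp) & sgn * tp > t_crit)
      for (comp in graph_components(members, nb_ok))
        best <- max(best, abs(sum(tp[comp])))
    }
    null_max[p_] <- best
  }
  for (i in seq_along(clusters)) {
    stat <- abs(clusters[[i]]$sum_t)
    clusters[[i]]$p <- if (exact) mean(null_max >= stat - 1e-12)
                       else (sum(null_max >= stat - 1e-12) + 1) / (n_perm + 1)
  }
  structure(list(clusters = clusters, t_map = t_obs, threshold_t = t_crit,
                 null_distribution = null_max, n_randomizations = n_perm,
                 exact = exact, n_subjects = n, seed = as.integer(seed)),
            class = "cluster_test_result")
}

#' @export
print.cluster_test_result <- function(x, ...) {
  cat(sprintf("cluster_test_result: %d cluster(s), threshold |t| > %.3f, %d %s randomizations\n",
              length(x$clusters), x$threshold_t, x$n_randomizations,
              if (x$exact) "exact" else "Monte-Carlo"))
  for (cl in x$clusters)
    cat(sprintf("  sign %+d, %d elements, sum t = %.2f, p = %.4f\n",
                cl$sign, length(cl$members), cl$sum_t, cl$p))
  invisible(x)
}

#' Export a cluster report as tab-delimited text
#'
#' @param result \code{cluster_test_result}.
#' @param path output path.
#' @return the report data frame, invisibly.
#' @export
write_cluster_report <- function(result, path) {
  cl <- result$clusters
  rep_df <- data.frame(
    cluster_id = seq_along(cl),
    sign = vapply(cl, function(c_) c_$sign, 1),
    n_elements = vapply(cl, function(c_) length(c_$members), 1L),
    sum_t = vapply(cl, function(c_) c_$sum_t, 1),
    p = vapply(cl, function(c_) c_$p, 1),
    members = vapply(cl, function(c_) paste(c_$members, collapse = ","), ""))
  utils::write.table(rep_df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(rep_df)
}

#' A-priori ROI band-power t tests
#'
#' Paired two-tail t tests of Attend Phoneme vs Attend Location, or
#' one-sample two-tail t tests of dB-normalized power against zero (polarity
#' vs Passive), per ROI, hemisphere, and band. Raw p values are reported
#' (the a-priori comparisons carry no multiplicity correction) and flagged
#' at 0.05 and 0.01.
#'
#' @param roi_power_table data frame with columns subject, roi, hemisphere,
#'   band, condition, value_db.
#' @param comparison "phoneme_vs_location" or "active_vs_zero".
#' @return data frame with one row per (roi, hemisphere, band[, condition]):
#'   t, df, p, sig05, sig01, flagged (zero variance).
#' @export
roi_band_tests <- function(roi_power_table,
                           comparison = c("phoneme_vs_location", "active_vs_zero")) {
  comparison <- match.arg(comparison)
  tab <- roi_power_table
  cells <- unique(tab[, c("roi", "hemisphere", "band")])
  out <- list()
  for (i in seq_len(nrow(cells))) {
    sub <- tab[tab$roi == cells$roi[i] & tab$hemisphere == cells$hemisphere[i] &
                 tab$band == cells$band[i], ]
    if (comparison == "phoneme_vs_location") {
      a <- sub[sub$condition == "attend_phoneme", ]
      b <- sub[sub$condition == "attend_location", ]
      if (!nrow(a) || !nrow(b)) data_error("missing condition cell for ROI %s", cells$roi[i])
      a <- a$value_db[order(a$subject)]; b <- b$value_db[order(b$subject)]
      if (length(a) < 2 || length(a) != length(b))
        data_error("unbalanced subjects in ROI %s", cells$roi[i])
      d <- a - b
      row <- one_t_row(d, cells[i, ])
      out[[length(out) + 1L]] <- row
    } else {
      for (cond in c("attend_phoneme", "attend_location")) {
        cc <- sub[sub$condition == cond, ]
        if (!nrow(cc)) data_error("missing condition cell for ROI %s", cells$roi[i])
        if (nrow(cc) < 2) data_error("need >= 2 subjects per cell")
        row <- one_t_row(cc$value_db[order(cc$subject)], cells[i, ])
        row$condition <- cond
        out[[length(out) + 1L]] <- row
      }
    }
  }
  do.call(rbind, out)
}

one_t_row <- function(x, cell) {
  if (stats::sd(x) <= 0) {
    data.frame(cell, t = NA_real_, df = length(x) - 1, p = NA_real_,
               sig05 = FALSE, sig01 = FALSE, flagged = TRUE, row.names = NULL)
  } else {
    tt <- stats::t.test(x, mu = 0)
    data.frame(cell, t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, sig05 = tt$p.value <= 0.05,
               sig01 = tt$p.value <= 0.01, flagged = FALSE, row.names = NULL)
  }
}
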