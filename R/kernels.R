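# The three site-by-site similarity kernels and their weighted combination.
#
# * seq: positionwise BLOSUM62 score of the 15-residue windows, min-max
#   normalized to [0, 1] over the training matrix.
# * ppi: Jaccard index of the two substrates' interaction-partner sets.
# * net: Gaussian kernel over the sites' rows in the site-by-kinase
#   adjacency (the network profile), with the bandwidth scaled by the mean
#   squared profile norm.

new_kernel <- function(values, source, meta = list()) {
  stopifnot(is.matrix(values))
  structure(values, source = source, meta = meta,
            class = c("ksr_kernel", class(values)))
}

#' @export
print.ksr_kernel <- function(x, ...) {
  cat(sprintf("<ksr_kernel:%s> %d x %d sites\n", attr(x, "source"),
              nrow(x), ncol(x)))
  invisible(x)
}

kernel_source <- function(k) attr(k, "source")
kernel_meta <- function(k) attr(k, "meta")

#' Sequence kernel over phosphosite windows
#'
#' Builds the raw pairwise BLOSUM62 window-similarity matrix and min-max
#' normalizes it to \[0, 1\] over all entries.  The (min, max) pair is kept
#' in the kernel metadata; pass it as `range` to score new windows against a
#' trained model on the same scale (values are then clipped to \[0, 1\]).
#'
#' @param windows Named character vector of 15-residue windows (names are
#'   site ids).
#' @param range Optional `c(min, max)` raw-score range from a previously
#'   built kernel; when given, it is applied instead of the matrix's own
#'   range and out-of-range values are clipped.
#' @param pad,width See [blosum_window_similarity()].
#' @return A `ksr_kernel` with `source = "seq"`.
#' @export
sequence_kernel <- function(windows, range = NULL, pad = "X", width = 15L) {
  if (length(windows) < 2) {
    abort("need at least two windows", class = "kinsub_argument_error")
  }
  s <- blosum_raw_matrix(windows, pad = pad, width = width)
  dimnames(s) <- list(names(windows), names(windows))
  new_kernel(normalize_seq(s, range), "seq",
             meta = list(range = range %||% range(s), pad = pad))
}

normalize_seq <- function(s, range = NULL) {
  r <- range %||% range(s)
  if (r[2] <= r[1]) {
    abort("degenerate sequence-score range: all pairwise scores identical",
          class = "kinsub_degenerate_error")
  }
  pmin(pmax((s - r[1]) / (r[2] - r[1]), 0), 1)
}

#' Jaccard index of two neighbour sets
#'
#' @param a,b Character vectors (interaction-partner sets); duplicates
#'   ignored.  Two empty sets have similarity 0, so substrates without any
#'   PPI evidence do not look maximally similar to each other.
#' @return Similarity in \[0, 1\].
#' @export
jaccard_similarity <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' PPI kernel over phosphosites
#'
#' Sites inherit their substrate's interaction-partner set; the kernel entry
#' is the Jaccard index of the two sets.  Sites on the same substrate are
#' maximally similar (1) whenever the substrate has at least one partner.
#'
#' @param sites Tibble with `site_id` and `substrate` columns.
#' @param ppi A `ksr_ppi` network.
#' @return A `ksr_kernel` with `source = "ppi"`.
#' @export
ppi_kernel <- function(sites, ppi) {
  subs <- unique(sites$substrate)
  nb <- lapply(subs, function(a) ppi_neighbors(ppi, a))
  j <- jaccard_matrix(nb, nb)
  dimnames(j) <- list(subs, subs)
  k <- j[sites$substrate, sites$substrate, drop = FALSE]
  dimnames(k) <- list(sites$site_id, sites$site_id)
  new_kernel(k, "ppi")
}

# dense Jaccard matrix between two lists of sets via a binary incidence
jaccard_matrix <- function(sets_a, sets_b) {
  prot <- unique(c(unlist(sets_a), unlist(sets_b)))
  inc <- function(sets) {
    m <- matrix(0, length(sets), length(prot))
    for (i in seq_along(sets)) m[i, match(sets[[i]], prot)] <- 1
    m
  }
  if (length(prot) == 0) {
    return(matrix(0, length(sets_a), length(sets_b)))
  }
  ma <- inc(sets_a); mb <- inc(sets_b)
  inter <- ma %*% t(mb)
  un <- outer(rowSums(ma), rowSums(mb), `+`) - inter
  out <- ifelse(un > 0, inter / un, 0)
  out
}

# cross-kernel rows for query substrates against training substrates
ppi_cross <- function(query_substrates, train_sites, ppi) {
  qs <- unique(query_substrates)
  ts <- unique(train_sites$substrate)
  j <- jaccard_matrix(lapply(qs, function(a) ppi_neighbors(ppi, a)),
                      lapply(ts, function(a) ppi_neighbors(ppi, a)))
  dimnames(j) <- list(qs, ts)
  j[query_substrates, train_sites$substrate, drop = FALSE]
}

#' Gaussian bandwidth for the network-profile kernel
#'
#' Scales a base bandwidth by the mean squared norm of the site profiles
#' (the average number of kinase links per site), so the kernel's reach
#' adapts to annotation density.
#'
#' @param Y Binary site-by-kinase adjacency matrix.
#' @param gamma_prime Base bandwidth (default 1).
#' @return The bandwidth `gamma_prime / mean(rowSums(Y^2))`.
#' @export
pskn_bandwidth <- function(Y, gamma_prime = 1) {
  stopifnot(gamma_prime > 0)
  m <- mean(rowSums(Y * Y))
  if (m == 0) {
    abort("all network profiles are zero: bandwidth undefined (division by zero)",
          class = "kinsub_degenerate_error")
  }
  gamma_prime / m
}

#' Network-profile (pSKN) kernel
#'
#' Gaussian kernel over the sites' binary kinase-annotation profiles:
#' `exp(-gamma * ||y_i - y_j||^2)`.  To keep a model's own labels out of its
#' features, the default mask policy removes the target kinase's column
#' before both the bandwidth and the kernel are computed.
#'
#' @param Y Binary site-by-kinase adjacency matrix (rownames = site ids).
#' @param gamma_prime Base bandwidth, see [pskn_bandwidth()].
#' @param mask_policy One of `"mask_target_column"` (drop the target
#'   kinase's column; the default), `"strict_zero_test_rows"` (additionally
#'   zero the profiles of `test_sites`), or `"none"`.
#' @param target_kinase Kinase whose column is masked (required unless
#'   `mask_policy = "none"`).
#' @param test_sites Site ids whose rows are zeroed under
#'   `"strict_zero_test_rows"`.
#' @param gamma Optional explicit bandwidth overriding [pskn_bandwidth()]
#'   (used in cross-validation, where the bandwidth comes from training
#'   rows only).
#' @return A `ksr_kernel` with `source = "net"`, unit diagonal, entries in
#'   (0, 1].
#' @export
pskn_kernel <- function(Y, gamma_prime = 1,
                        mask_policy = c("mask_target_column",
                                        "strict_zero_test_rows", "none"),
                        target_kinase = NULL, test_sites = NULL,
                        gamma = NULL) {
  mask_policy <- match.arg(mask_policy)
  Ym <- mask_profiles(Y, mask_policy, target_kinase, test_sites)
  g <- gamma %||% pskn_bandwidth(Ym, gamma_prime)
  k <- gaussian_profile_kernel(Ym, Ym, g)
  dimnames(k) <- list(rownames(Y), rownames(Y))
  new_kernel(k, "net",
             meta = list(gamma = g, gamma_prime = gamma_prime,
                         mask_policy = mask_policy,
                         target_kinase = target_kinase))
}

mask_profiles <- function(Y, mask_policy, target_kinase = NULL,
                          test_sites = NULL) {
  if (mask_policy == "none") return(Y)
  if (is.null(target_kinase)) {
    abort("mask policy needs a target_kinase", class = "kinsub_argument_error")
  }
  if (!target_kinase %in% colnames(Y)) {
    abort(sprintf("kinase %s not in adjacency", target_kinase),
          class = "kinsub_reference_error")
  }
  Ym <- Y[, setdiff(colnames(Y), target_kinase), drop = FALSE]
  if (mask_policy == "strict_zero_test_rows" && length(test_sites) > 0) {
    Ym[rownames(Ym) %in% test_sites, ] <- 0
  }
  Ym
}

gaussian_profile_kernel <- function(A, B, gamma) {
  ra <- rowSums(A * A); rb <- rowSums(B * B)
  d2 <- outer(ra, rb, `+`) - 2 * A %*% t(B)
  d2[d2 < 0] <- 0  # numerical guard
  exp(-gamma * d2)
}

#' Weighted combination of site kernels
#'
#' Elementwise nonnegative combination `K = sum(w_phi * K_phi)`.  With the
#' default equal weights this is the unweighted average of the supplied
#' kernels; weights are renormalized to sum to 1 so ablation subsets stay on
#' the same scale.
#'
#' @param kernels List of `ksr_kernel` objects sharing the same site order.
#' @param weights Nonnegative numeric vector, one per kernel (default
#'   equal).  Renormalized to sum to 1.
#' @return A `ksr_kernel` with `source = "combined"`.
#' @export
combine_kernels <- function(kernels, weights = NULL) {
  stopifnot(length(kernels) >= 1)
  weights <- weights %||% rep(1 / length(kernels), length(kernels))
  if (length(weights) != length(kernels) || any(weights < 0)) {
    abort("need one nonnegative weight per kernel",
          class = "kinsub_argument_error")
  }
  if (sum(weights) == 0) {
    abort("at least one kernel weight must be positive",
          class = "kinsub_argument_error")
  }
  weights <- weights / sum(weights)
  ord <- rownames(kernels[[1]])
  for (k in kernels[-1]) {
    if (!identical(rownames(k), ord) || !identical(colnames(k), colnames(kernels[[1]]))) {
      abort("kernels do not share the same site order",
            class = "kinsub_alignment_error")
    }
  }
  out <- Reduce(`+`, Map(function(k, w) unclass(k) * w, kernels, weights))
  new_kernel(out, "combined",
             meta = list(weights = setNames(weights,
                                            vapply(kernels, kernel_source, "")),
                         components = lapply(kernels, kernel_meta)))
}

#' Write a kernel matrix as tab-separated text
#'
#' Square matrix with a header row and first column of site ids, so cached
#' kernels can be reused between pipeline stages.
#'
#' @param kernel A `ksr_kernel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kernel <- function(kernel, path) {
  df <- as.data.frame(unclass(kernel))
  df <- cbind(site_id = rownames(kernel), df)
  readr::write_tsv(tibble::as_tibble(df), path)
  invisible(path)
}

#' Read a kernel matrix written by [write_kernel()]
#'
#' @param path Path to the tab-separated matrix.
#' @param source Provenance tag to attach (`"seq"`, `"ppi"`, `"net"`,
#'   `"combined"`).
#' @return A `ksr_kernel`.
#' @export
read_kernel <- function(path, source = "combined") {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  new_kernel(m, source)
}
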