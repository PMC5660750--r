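# Per-kinase kernel ridge classifier.
#
# Labels are 0/1; the fit solves (K + lambda I) alpha = y by Cholesky
# factorization (with a one-shot 1e-8 jitter retry for borderline
# conditioning) and a query site is scored as alpha' k_x, where k_x holds
# the combined kernel values between the query and the training sites.

#' Model configuration
#'
#' @param lambda Ridge regularizer (> 0, default 1).
#' @param kernel_weights Named nonnegative weights over
#'   `c("seq", "ppi", "net")`; only the named components enter the combined
#'   kernel (ablations drop names).  Default equal thirds.
#' @param gamma_prime Base bandwidth of the network-profile kernel.
#' @param mask_policy Leakage policy for the network kernel, see
#'   [pskn_kernel()].
#' @param min_positives Minimum annotated sites for a kinase to be modeled
#'   (default 15).
#' @param pad Pad character of the sequence windows.
#' @return A `ksr_config` list.
#' @export
ksr_config <- function(lambda = 1,
                       kernel_weights = c(seq = 1/3, ppi = 1/3, net = 1/3),
                       gamma_prime = 1,
                       mask_policy = "mask_target_column",
                       min_positives = 15L, pad = "X") {
  stopifnot(lambda > 0, all(kernel_weights >= 0), sum(kernel_weights) > 0,
            gamma_prime > 0, min_positives >= 1)
  if (is.null(names(kernel_weights)) ||
      !all(names(kernel_weights) %in% c("seq", "ppi", "net"))) {
    abort("kernel_weights must be named with seq/ppi/net",
          class = "kinsub_argument_error")
  }
  structure(list(lambda = lambda, kernel_weights = kernel_weights,
                 gamma_prime = gamma_prime, mask_policy = mask_policy,
                 min_positives = as.integer(min_positives), pad = pad),
            class = "ksr_config")
}

# stable symmetric solve of (K + lambda I) alpha = y
ridge_solve <- function(K, y, lambda) {
  n <- nrow(K)
  A <- unclass(K) + diag(lambda, n)
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) {
    warn("ridge system not positive definite; retrying with 1e-8 jitter")
    ch <- tryCatch(chol(A + diag(1e-8, n)), error = function(e) {
      abort(paste("ridge system numerically singular;",
                  "increase lambda or enable PSD clipping"),
            class = "kinsub_solver_error")
    })
  }
  alpha <- backsolve(ch, backsolve(ch, y, transpose = TRUE))
  resid <- max(abs(A %*% alpha - y))
  if (resid > 1e-8) {
    warn(sprintf("ridge solve residual %.2e exceeds 1e-8", resid))
  }
  drop(alpha)
}

#' Fit a kernel ridge classifier for one kinase
#'
#' @param K_train Combined training kernel (square `ksr_kernel` or matrix)
#'   over the training sites.
#' @param y Binary 0/1 label vector aligned with `K_train`.
#' @param lambda Ridge regularizer (> 0).
#' @param kinase Optional kinase name carried in the model.
#' @return A `ksr_krr` model holding the dual coefficients `alpha`.
#' @export
krr_fit <- function(K_train, y, lambda = 1, kinase = NULL) {
  stopifnot(nrow(K_train) == ncol(K_train), length(y) == nrow(K_train),
            lambda > 0, all(y %in% c(0, 1)))
  alpha <- ridge_solve(K_train, y, lambda)
  structure(list(kinase = kinase, alpha = alpha, lambda = lambda,
                 site_ids = rownames(K_train), n_pos = sum(y),
                 n_neg = sum(1 - y)),
            class = "ksr_krr")
}

#' Score query sites from their kernel rows
#'
#' @param object A `ksr_krr` model.
#' @param k_x Numeric vector (one query) or matrix (queries x training
#'   sites) of combined kernel values against the training sites, in the
#'   model's training-site order.
#' @param ... Unused.
#' @return Numeric score(s); higher means more likely a substrate site of
#'   the kinase.
#' @export
predict.ksr_krr <- function(object, k_x, ...) {
  if (is.null(dim(k_x))) k_x <- matrix(k_x, nrow = 1)
  if (ncol(k_x) != length(object$alpha)) {
    abort(sprintf("k_x has %d columns but the model has %d training sites",
                  ncol(k_x), length(object$alpha)),
          class = "kinsub_alignment_error")
  }
  drop(k_x %*% object$alpha)
}

#' @export
print.ksr_krr <- function(x, ...) {
  cat(sprintf("<ksr_krr> kinase %s: %d sites (%d+/%d-), lambda %.3g\n",
              x$kinase %||% "?", length(x$alpha), x$n_pos, x$n_neg,
              x$lambda))
  invisible(x)
}

#' @export
tidy.ksr_krr <- function(x, ...) {
  tibble(site_id = x$site_ids %||% as.character(seq_along(x$alpha)),
         alpha = x$alpha)
}

#' @export
glance.ksr_krr <- function(x, ...) {
  tibble(kinase = x$kinase %||% NA_character_,
         n_sites = length(x$alpha), n_pos = x$n_pos, n_neg = x$n_neg,
         lambda = x$lambda, alpha_norm = sqrt(sum(x$alpha^2)))
}

# component kernels shared across kinases for a full-data fit
training_kernels <- function(bundle, config) {
  w <- setNames(bundle$sites$window, bundle$sites$site_id)
  list(
    seq = if ("seq" %in% names(config$kernel_weights))
      sequence_kernel(w, pad = config$pad),
    ppi = if ("ppi" %in% names(config$kernel_weights))
      ppi_kernel(bundle$sites, bundle$ppi)
  )
}

#' Train one ridge model per eligible kinase
#'
#' Builds the component kernels, applies the leakage mask of the network
#' kernel per target kinase, combines them with the configured weights and
#' fits a ridge classifier for every kinase with at least
#' `config$min_positives` annotated sites.
#'
#' @param bundle A `ksr_bundle`.
#' @param config A [ksr_config()].
#' @return A `ksr_models` object: named list of per-kinase models plus the
#'   shared training context needed to score new sites.
#' @export
train_kinase_models <- function(bundle, config = ksr_config()) {
  kinases <- select_model_kinases(bundle$adjacency, config$min_positives)
  if (length(kinases) == 0) {
    warn("no kinase reaches the minimum number of positive sites")
  }
  shared <- training_kernels(bundle, config)
  models <- lapply(kinases, function(kin) {
    parts <- shared[!vapply(shared, is.null, TRUE)]
    if ("net" %in% names(config$kernel_weights)) {
      parts$net <- pskn_kernel(bundle$adjacency,
                               gamma_prime = config$gamma_prime,
                               mask_policy = config$mask_policy,
                               target_kinase = kin)
    }
    Kc <- combine_kernels(unname(parts),
                          config$kernel_weights[names(parts)])
    fit <- krr_fit(Kc, label_vector(bundle$adjacency, kin),
                   lambda = config$lambda, kinase = kin)
    fit$kernel_meta <- kernel_meta(Kc)
    fit
  })
  structure(list(models = setNames(models, kinases), config = config,
                 train_sites = bundle$sites,
                 train_adjacency = bundle$adjacency,
                 ppi = bundle$ppi, flank = bundle$flank, pad = bundle$pad),
            class = "ksr_models")
}

#' @export
print.ksr_models <- function(x, ...) {
  cat(sprintf("<ksr_models> %d kinase model(s) over %d training sites\n",
              length(x$models), nrow(x$train_sites)))
  invisible(x)
}

#' @export
glance.ksr_models <- function(x, ...) {
  dplyr::bind_rows(lapply(x$models, glance))
}

#' Score query sites against every trained kinase model
#'
#' Component kernel rows between each query site and the training sites are
#' computed with the stored normalization metadata (sequence min/max with
#' clipping) and each model's mask policy; a query substrate absent from
#' the PPI network contributes an empty partner set.  Query sites present
#' in the training adjacency reuse their known profiles for the network
#' kernel (minus the masked column); unknown sites get a zero profile.
#'
#' @param models A `ksr_models` object.
#' @param query_sites Tibble with `site_id`, `substrate`, `position`,
#'   `residue` and optionally `window` (computed from `substrates` if
#'   absent).
#' @param substrates Optional substrate tibble for window extraction.
#' @return Tibble `(site_id, kinase, score)` sorted by kinase then
#'   descending score, ties broken by site id.
#' @export
score_sites <- function(models, query_sites, substrates = NULL) {
  if (length(models$models) == 0) {
    return(tibble(site_id = character(), kinase = character(),
                  score = double()))
  }
  if (!"window" %in% names(query_sites)) {
    if (is.null(substrates)) {
      abort("query sites need a window column or a substrates table",
            class = "kinsub_argument_error")
    }
    query_sites <- attach_windows(query_sites, substrates,
                                  flank = models$flank, pad = models$pad)
  }
  config <- models$config
  train <- models$train_sites
  wts <- config$kernel_weights

  seq_raw <- if ("seq" %in% names(wts))
    blosum_raw_matrix(setNames(query_sites$window, query_sites$site_id),
                      setNames(train$window, train$site_id),
                      pad = config$pad)
  ppi_x <- if ("ppi" %in% names(wts)) {
    m <- ppi_cross(query_sites$substrate, train, models$ppi)
    dimnames(m) <- list(query_sites$site_id, train$site_id)
    m
  }
  Y <- models$train_adjacency
  # known query sites keep their profiles; unknown sites are all-zero
  Yq <- matrix(0, nrow(query_sites), ncol(Y),
               dimnames = list(query_sites$site_id, colnames(Y)))
  known <- intersect(query_sites$site_id, rownames(Y))
  Yq[known, ] <- Y[known, , drop = FALSE]

  out <- purrr::map_dfr(models$models, function(m) {
    parts <- list(); pw <- c()
    if (!is.null(seq_raw)) {
      rng <- find_meta(m$kernel_meta, "range")
      parts <- c(parts, list(normalize_seq(seq_raw, rng)))
      pw <- c(pw, wts[["seq"]])
    }
    if (!is.null(ppi_x)) {
      parts <- c(parts, list(ppi_x))
      pw <- c(pw, wts[["ppi"]])
    }
    if ("net" %in% names(wts)) {
      keep <- if (config$mask_policy == "none") colnames(Y)
              else setdiff(colnames(Y), m$kinase)
      g <- find_meta(m$kernel_meta, "gamma")
      kn <- gaussian_profile_kernel(Yq[, keep, drop = FALSE],
                                    Y[, keep, drop = FALSE], g)
      parts <- c(parts, list(kn))
      pw <- c(pw, wts[["net"]])
    }
    pw <- pw / sum(pw)
    kx <- Reduce(`+`, Map(`*`, parts, pw))
    tibble(site_id = query_sites$site_id, kinase = m$kinase,
           score = predict(m, kx))
  })
  dplyr::arrange(out, .data$kinase, dplyr::desc(.data$score), .data$site_id)
}

# pull a stored normalization value out of combined-kernel metadata
find_meta <- function(meta, field) {
  for (comp in meta$components) {
    if (!is.null(comp[[field]])) return(comp[[field]])
  }
  NULL
}

#' Serialize trained models to structured text
#'
#' Writes a single JSON archive holding, per kinase, the dual coefficients,
#' training-site ids, configuration and kernel normalization metadata.
#'
#' @param models A `ksr_models` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_models <- function(models, path) {
  cfg <- unclass(models$config)
  cfg$kernel_weights <- as.list(cfg$kernel_weights)  # keep names in JSON
  payload <- list(
    schema = "kinsub-models/1",
    config = cfg,
    train_sites = models$train_sites,
    train_adjacency = list(values = unname(models$train_adjacency),
                           site_ids = rownames(models$train_adjacency),
                           kinases = colnames(models$train_adjacency)),
    ppi_edges = models$ppi$edges,
    ppi_cutoff = models$ppi$cutoff,
    flank = models$flank, pad = models$pad,
    models = lapply(models$models, function(m) {
      list(kinase = m$kinase, alpha = m$alpha, lambda = m$lambda,
           site_ids = m$site_ids, n_pos = m$n_pos, n_neg = m$n_neg,
           kernel_meta = m$kernel_meta)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load models written by [write_models()]
#'
#' @param path Path to the JSON archive.
#' @return A `ksr_models` object.
#' @export
read_models <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$schema, "kinsub-models/1")) {
    abort(sprintf("unrecognized model archive schema: %s", p$schema),
          class = "kinsub_parse_error")
  }
  adj <- as.matrix(p$train_adjacency$values)
  dimnames(adj) <- list(p$train_adjacency$site_ids,
                        p$train_adjacency$kinases)
  p$config$kernel_weights <- unlist(p$config$kernel_weights)
  cfg <- do.call(ksr_config, p$config)
  mods <- lapply(seq_len(nrow_models(p$models)), function(i) {
    m <- extract_model(p$models, i)
    structure(m, class = "ksr_krr")
  })
  names(mods) <- vapply(mods, function(m) m$kinase, "")
  structure(list(models = mods, config = cfg,
                 train_sites = tibble::as_tibble(p$train_sites),
                 train_adjacency = adj,
                 ppi = ppi_from_edges(tibble::as_tibble(p$ppi_edges),
                                      cutoff = p$ppi_cutoff),
                 flank = p$flank, pad = p$pad),
            class = "ksr_models")
}

nrow_models <- function(models_field) length(models_field)

extract_model <- function(models_field, i) {
  m <- models_field[[i]]
  m$alpha <- as.numeric(m$alpha)
  m$site_ids <- as.character(m$site_ids)
  m
}
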