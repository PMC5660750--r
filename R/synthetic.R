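# Seeded synthetic datasets with the statistical structure the predictor
# assumes: planted sequence motifs per kinase, correlated kinase-annotation
# profiles (partner co-assignment), and a coherent PPI layer (per-kinase hub
# proteins shared by that kinase's substrates).

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Specification of a synthetic benchmark dataset
#'
#' The defaults describe the benchmark used throughout the package's own
#' evaluation: 150 substrates with 2 sites each (300 sites), 5 kinases with
#' 30 positives apiece, a moderately informative sequence motif
#' (`motif_strength = 0.7`), a designated partner kinase co-assigned to
#' half of each kinase's positive sites (`kinase_overlap = 0.5`), and PPI
#' hub attachment for half of each kinase's substrates
#' (`ppi_coherence = 0.5`).
#'
#' @param n_substrates Number of substrate proteins.
#' @param sites_per_substrate Phosphosites per substrate (windows are
#'   spaced so they never overlap or touch a terminus).
#' @param n_kinases Number of kinases.
#' @param positives_per_kinase Annotated sites per kinase, sampled
#'   site-wise and independently across kinases.
#' @param motif_strength Probability that a positive site's window is drawn
#'   from the kinase's position-specific residue preferences rather than
#'   background.
#' @param kinase_overlap Probability that a positive site of kinase `j` is
#'   co-assigned to `j`'s designated partner kinase (the cyclic successor),
#'   inducing correlated network profiles.
#' @param ppi_coherence Probability that a substrate carrying positives of
#'   kinase `j` attaches to `j`'s hub-protein set in the PPI layer.
#' @param n_informative Number of motif-informative flank positions per
#'   kinase (default 4).
#' @param pref_prob Probability of the preferred residue at an informative
#'   position of a motif-drawn window (default 0.8).
#' @param n_hubs Hub proteins per kinase (default 12).
#' @param noise_edges Background PPI partners per substrate (default 8).
#' @param background Residue sampling probabilities (default uniform over
#'   the 20 standard amino acids).
#' @param seed Integer seed governing every draw.
#' @return A `ksr_synth_spec` list.
#' @export
synth_spec <- function(n_substrates = 150L, sites_per_substrate = 2L,
                       n_kinases = 5L, positives_per_kinase = 30L,
                       motif_strength = 0.7, kinase_overlap = 0.5,
                       ppi_coherence = 0.5, n_informative = 4L,
                       pref_prob = 0.8, n_hubs = 12L, noise_edges = 8L,
                       background = NULL, seed = 1L) {
  probs <- c(motif_strength, kinase_overlap, ppi_coherence, pref_prob)
  stopifnot(all(probs >= 0 & probs <= 1), n_substrates >= 1,
            sites_per_substrate >= 1, n_kinases >= 1,
            positives_per_kinase >= 1)
  if (positives_per_kinase > n_substrates * sites_per_substrate) {
    abort("more positives requested than sites exist",
          class = "kinsub_argument_error")
  }
  background <- background %||% setNames(rep(1 / 20, 20), AA20)
  structure(list(n_substrates = as.integer(n_substrates),
                 sites_per_substrate = as.integer(sites_per_substrate),
                 n_kinases = as.integer(n_kinases),
                 positives_per_kinase = as.integer(positives_per_kinase),
                 motif_strength = motif_strength,
                 kinase_overlap = kinase_overlap,
                 ppi_coherence = ppi_coherence,
                 n_informative = as.integer(n_informative),
                 pref_prob = pref_prob, n_hubs = as.integer(n_hubs),
                 noise_edges = as.integer(noise_edges),
                 background = background, seed = as.integer(seed)),
            class = "ksr_synth_spec")
}

sample_bg <- function(n, background) {
  sample(names(background), n, replace = TRUE, prob = background)
}

#' Generate a synthetic dataset bundle
#'
#' Deterministic given `spec$seed`.  Ground truth (motifs, partner map, hub
#' sets, noise-free assignments) is attached as the `"truth"` attribute.
#'
#' @param spec A [synth_spec()].
#' @return A `ksr_bundle`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "ksr_synth_spec"))
  withr::with_seed(derive_seed(spec$seed, 7L), generate_dataset_impl(spec))
}

generate_dataset_impl <- function(spec) {
  flank <- 7L
  width <- 2L * flank + 1L
  spacing <- width + 2L
  len <- spacing * spec$sites_per_substrate
  acc <- sprintf("SUB%03d", seq_len(spec$n_substrates))
  kin <- sprintf("KIN%02d", seq_len(spec$n_kinases))

  # background sequences with S/T/Y phosphoacceptors at fixed spaced slots
  seqs <- vapply(acc, function(a) {
    paste(sample_bg(len, spec$background), collapse = "")
  }, "")
  pos <- flank + 1L + spacing * (seq_len(spec$sites_per_substrate) - 1L)
  sites <- tidyr::expand_grid(substrate = acc, position = pos)
  acceptors <- sample(c("S", "T", "Y"), nrow(sites), replace = TRUE,
                      prob = c(0.45, 0.35, 0.20))
  for (i in seq_len(nrow(sites))) {
    substr(seqs[sites$substrate[i]], sites$position[i],
           sites$position[i]) <- acceptors[i]
  }

  # per-kinase motif: acceptor preference + informative flank positions
  motifs <- lapply(kin, function(k) {
    list(acceptor = sample(c("S", "T", "Y"), 1, prob = c(0.45, 0.35, 0.20)),
         positions = sort(sample(setdiff(seq_len(width), flank + 1L),
                                 spec$n_informative)),
         preferred = sample(AA20, spec$n_informative, replace = TRUE))
  })
  names(motifs) <- kin
  partner <- if (spec$n_kinases > 1) {
    setNames(kin[c(seq_len(spec$n_kinases)[-1], 1L)], kin)
  } else {
    setNames(kin, kin)
  }

  # positives sampled site-wise and independently across kinases, so a
  # dataset with every signal knob at zero carries no label structure at all
  site_id_of <- function(s, p) paste0(s, "_", p)
  all_ids <- site_id_of(sites$substrate, sites$position)
  links <- list()
  substrates_of <- list()
  for (k in kin) {
    picked <- sample(all_ids, spec$positives_per_kinase)
    substrates_of[[k]] <- unique(sub("_[0-9]+$", "", picked))
    links[[k]] <- tibble(site_id = picked, kinase = k)
  }
  links <- dplyr::bind_rows(links)

  # plant motif windows: rewrite the window region of each positive site
  sites$site_id <- site_id_of(sites$substrate, sites$position)
  for (k in kin) {
    m <- motifs[[k]]
    for (sid in links$site_id[links$kinase == k]) {
      row <- sites[sites$site_id == sid, ]
      if (stats::runif(1) >= spec$motif_strength) next
      win <- sample_bg(width, spec$background)
      win[flank + 1L] <- m$acceptor
      use_pref <- stats::runif(spec$n_informative) < spec$pref_prob
      win[m$positions[use_pref]] <- m$preferred[use_pref]
      s <- seqs[row$substrate]
      substr(s, row$position - flank, row$position + flank) <-
        paste(win, collapse = "")
      seqs[row$substrate] <- s
    }
  }

  # partner co-assignment induces correlated network profiles
  if (spec$n_kinases > 1 && spec$kinase_overlap > 0) {
    co <- links[stats::runif(nrow(links)) < spec$kinase_overlap, ,
                drop = FALSE]
    co$kinase <- unname(partner[co$kinase])
    links <- dplyr::distinct(dplyr::bind_rows(links, co))
  }

  # PPI layer: per-substrate background partners + per-kinase hub sets
  pool <- sprintf("P%03d", seq_len(150L))
  hubs <- lapply(kin, function(k)
    sprintf("HUB_%s_%02d", k, seq_len(spec$n_hubs)))
  names(hubs) <- kin
  edges <- list()
  for (a in acc) {
    partners <- sample(pool, spec$noise_edges)
    edges[[a]] <- tibble(protein_a = a, protein_b = partners,
                         score = round(stats::runif(spec$noise_edges, 0.4, 1), 3))
  }
  for (k in kin) {
    for (a in substrates_of[[k]]) {
      if (stats::runif(1) < spec$ppi_coherence) {
        edges[[paste(a, k)]] <- tibble(
          protein_a = a, protein_b = hubs[[k]],
          score = round(stats::runif(spec$n_hubs, 0.5, 1), 3))
      }
    }
  }
  # a few below-cutoff edges so the confidence filter has work to do
  low <- tibble(protein_a = sample(acc, 3L * spec$n_substrates,
                                   replace = TRUE),
                protein_b = sample(pool, 3L * spec$n_substrates,
                                   replace = TRUE),
                score = round(stats::runif(3L * spec$n_substrates, 0.05, 0.35), 3))
  ppi <- ppi_from_edges(dplyr::bind_rows(c(unname(edges), list(low))),
                        cutoff = 0.4)

  site_tbl <- tibble(site_id = sites$site_id, substrate = sites$substrate,
                     position = sites$position) |>
    dplyr::mutate(residue = unname(substr(seqs[.data$substrate],
                                          .data$position, .data$position)))
  bundle <- ksr_bundle(tibble(accession = acc, sequence = unname(seqs)),
                       site_tbl, links, ppi = ppi)
  attr(bundle, "truth") <- list(motifs = motifs, partner = partner,
                                hubs = hubs, substrates_of = substrates_of,
                                spec = spec)
  bundle
}

#' Hand-auditable six-site micro example
#'
#' A fixed bundle with 6 phosphosites on 4 substrates and 3 kinases whose
#' kernels can all be recomputed by hand: the adjacency is the constant
#' matrix documented below, the PPI network has seven edges (one below the
#' 0.4 cutoff), and the windows sit fully inside their sequences.
#'
#' Adjacency (rows = sites s1..s6, columns = kinases KA, KB, KC):
#' \preformatted{
#'   s1 (SUBA_8)  1 0 0
#'   s2 (SUBA_23) 1 1 0
#'   s3 (SUBB_8)  0 1 0
#'   s4 (SUBB_23) 0 1 1
#'   s5 (SUBC_8)  0 0 1
#'   s6 (SUBD_8)  1 0 1
#' }
#'
#' @return A `ksr_bundle`.
#' @export
micro_example <- function() {
  substrates <- tibble(
    accession = c("SUBA", "SUBB", "SUBC", "SUBD"),
    sequence = c("AGCDEFGSRKLMNPQAGCDEFGTRKLMNPQAG",
                 "MKVLANRSDEQGHIWMKVLANRYDEQGHIWMK",
                 "PPPQRSTSPPPQRST",
                 "WWCDEFGYHIKLMNP"))
  sites <- tibble(
    substrate = c("SUBA", "SUBA", "SUBB", "SUBB", "SUBC", "SUBD"),
    position = c(8L, 23L, 8L, 23L, 8L, 8L))
  sites$site_id <- paste0(sites$substrate, "_", sites$position)
  sites$residue <- substr(substrates$sequence[match(sites$substrate,
                                                    substrates$accession)],
                          sites$position, sites$position)
  links <- tibble(
    site_id = c("SUBA_8", "SUBA_23", "SUBA_23", "SUBB_8", "SUBB_23",
                "SUBB_23", "SUBC_8", "SUBD_8", "SUBD_8"),
    kinase = c("KA", "KA", "KB", "KB", "KB", "KC", "KC", "KA", "KC"))
  edges <- tibble(
    protein_a = c("SUBA", "SUBA", "SUBB", "SUBC", "SUBC", "SUBD", "SUBA"),
    protein_b = c("SUBB", "P1", "P1", "P2", "P1", "P3", "P3"),
    score = c(0.8, 0.9, 0.5, 0.45, 0.6, 0.9, 0.2))
  ksr_bundle(substrates, sites, links, ppi = ppi_from_edges(edges, 0.4))
}
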