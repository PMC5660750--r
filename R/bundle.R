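# DatasetBundle: substrates + sites + links + adjacency + PPI in one object.

#' Assemble a dataset bundle
#'
#' Bundles substrate sequences, phosphosites, site-kinase links, the
#' adjacency matrix and the PPI network, validating cross-references.  An
#' optional cluster map (member accession -> representative) applies an
#' externally computed redundancy reduction: only sites on representative
#' substrates are kept.
#'
#' @param substrates Tibble with `accession`, `sequence`.
#' @param sites Tibble with `site_id`, `substrate`, `position`, `residue`
#'   (windows are added if absent).
#' @param links Tibble with `site_id`, `kinase`.
#' @param ppi A `ksr_ppi` network (default: empty network).
#' @param cluster_map Optional named character vector from
#'   [read_cluster_map()].
#' @param flank,pad Window parameters.
#' @return A `ksr_bundle` object with elements `substrates`, `sites`,
#'   `links`, `adjacency`, `ppi`.
#' @export
ksr_bundle <- function(substrates, sites, links,
                       ppi = ppi_from_edges(tibble(protein_a = character(),
                                                   protein_b = character(),
                                                   score = double())),
                       cluster_map = NULL, flank = 7L, pad = "X") {
  if (!is.null(cluster_map)) {
    rep_of <- function(a) ifelse(a %in% names(cluster_map), cluster_map[a], a)
    keep <- substrates$accession == rep_of(substrates$accession)
    substrates <- substrates[keep, , drop = FALSE]
    sites <- sites[sites$substrate %in% substrates$accession, , drop = FALSE]
    links <- links[links$site_id %in% sites$site_id, , drop = FALSE]
  }
  n_dup <- sum(duplicated(links))
  if (n_dup > 0) {
    inform(sprintf("deduplicated %d repeated site-kinase link(s)", n_dup))
    links <- dplyr::distinct(links)
  }
  if (!"window" %in% names(sites)) {
    sites <- attach_windows(sites, substrates, flank = flank, pad = pad)
  }
  kinases <- unique(links$kinase)
  adjacency <- build_adjacency(sites$site_id, kinases, links)
  b <- structure(list(substrates = substrates, sites = sites, links = links,
                      adjacency = adjacency, ppi = ppi,
                      flank = flank, pad = pad),
                 class = "ksr_bundle")
  validate_bundle(b)
}

validate_bundle <- function(b) {
  stopifnot(inherits(b, "ksr_bundle"))
  if (!all(b$sites$substrate %in% b$substrates$accession)) {
    abort("site references a substrate missing from the sequence set",
          class = "kinsub_reference_error")
  }
  if (ncol(b$adjacency) > 0 && any(colSums(b$adjacency) == 0)) {
    abort("adjacency contains a kinase with no link",
          class = "kinsub_reference_error")
  }
  if (sum(b$adjacency) != nrow(b$links)) {
    abort("adjacency sum does not match the number of deduplicated links",
          class = "kinsub_consistency_error")
  }
  b
}

#' @export
print.ksr_bundle <- function(x, ...) {
  cat(sprintf(
    "<ksr_bundle> %d substrates, %d sites, %d kinases, %d links, %d PPI edges\n",
    nrow(x$substrates), nrow(x$sites), ncol(x$adjacency), nrow(x$links),
    nrow(x$ppi$edges)))
  invisible(x)
}

#' Write a bundle to its three on-disk files
#'
#' Writes `substrates.fasta`, `sites.tsv` and `ppi.tsv` under `dir`.
#'
#' @param bundle A `ksr_bundle`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(fasta = file.path(dir, "substrates.fasta"),
             sites = file.path(dir, "sites.tsv"),
             ppi = file.path(dir, "ppi.tsv"))
  write_substrate_fasta(bundle$substrates, paths[["fasta"]])
  write_site_table(bundle$sites, bundle$links, paths[["sites"]])
  write_ppi_edges(bundle$ppi, paths[["ppi"]])
  invisible(paths)
}

#' Read a bundle from FASTA + site table + PPI edge list
#'
#' @param fasta,sites,ppi File paths (see [write_bundle()] for the layout).
#' @param cutoff PPI confidence cutoff on the 0-1 scale.
#' @param cluster_map Optional path to a cluster map file.
#' @param residue_filter Passed to [read_site_table()].
#' @param flank,pad Window parameters.
#' @return A `ksr_bundle`.
#' @export
read_bundle <- function(fasta, sites, ppi, cutoff = 0.4, cluster_map = NULL,
                        residue_filter = c("S", "T", "Y"),
                        flank = 7L, pad = "X") {
  subs <- read_substrate_fasta(fasta)
  st <- read_site_table(sites, substrates = subs,
                        residue_filter = residue_filter,
                        flank = flank, pad = pad)
  net <- read_ppi_edges(ppi, cutoff = cutoff)
  cm <- if (!is.null(cluster_map)) read_cluster_map(cluster_map)
  ksr_bundle(subs, st$sites, st$links, ppi = net, cluster_map = cm,
             flank = flank, pad = pad)
}
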