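# Parsing of substrate sequences, phosphosite annotations and PPI edges into
# the internal data model.  All coordinates are 1-based (UniProt convention).

#' Read substrate sequences from a FASTA file
#'
#' @param path Path to a (multi-)FASTA file of amino-acid sequences.
#' @return A tibble with columns `accession` (description line up to the
#'   first whitespace) and `sequence` (uppercase).
#' @export
read_substrate_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  acc <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(acc)) {
    abort(sprintf("duplicate accession(s) in %s: %s", path,
                  paste(unique(acc[duplicated(acc)]), collapse = ", ")),
          class = "kinsub_parse_error")
  }
  tibble(accession = acc, sequence = unname(toupper(as.character(aa))))
}

#' Write substrate sequences to FASTA
#'
#' @param substrates Tibble with `accession` and `sequence` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_substrate_fasta <- function(substrates, path) {
  aa <- Biostrings::AAStringSet(setNames(substrates$sequence,
                                         substrates$accession))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Extract the local sequence window around a phosphosite
#'
#' Returns the `2 * flank + 1` residue window centred on `position`
#' (1-based).  Positions that fall outside the protein are filled with the
#' pad character, which later scores 0 in the sequence kernel.
#'
#' @param sequence Amino-acid string (or a vector, recycled against
#'   `position`).
#' @param position 1-based site position(s) within `sequence`.
#' @param flank Number of residues on each side (default 7, giving the
#'   15-residue window).
#' @param pad Pad character for out-of-range positions (default `"X"`).
#' @param accession Optional accession used in error messages.
#' @return Character vector of windows of length `2 * flank + 1`.
#' @examples
#' extract_window("SAAAAAAAA", 1)  # "XXXXXXXSAAAAAAA"
#' @export
extract_window <- function(sequence, position, flank = 7L, pad = "X",
                           accession = NULL) {
  n <- nchar(sequence)
  bad <- position < 1L | position > n
  if (any(bad)) {
    who <- if (is.null(accession)) "sequence" else accession[bad][1]
    abort(sprintf("position %d out of range 1..%d for %s",
                  position[bad][1], n[bad][1], who),
          class = "kinsub_position_error")
  }
  padded <- paste0(strrep(pad, flank), sequence, strrep(pad, flank))
  substr(rep(padded, length.out = length(position)),
         position, position + 2L * flank)
}

#' Read a phosphosite annotation table
#'
#' Expects a tab-separated file with a mandatory header and (at least) the
#' columns `substrate`, `position`, `residue`, `kinase`; extra columns are
#' ignored.  One site is kept per unique (substrate, position); site-kinase
#' links are deduplicated.  Rows whose residue is not in `residue_filter`
#' are dropped with a message.
#'
#' @param path Path to the site table.
#' @param substrates Optional substrate tibble (from
#'   [read_substrate_fasta()]); when given, each site's residue is checked
#'   against the sequence and windows are extracted.
#' @param residue_filter Characters accepted as phosphoacceptors
#'   (default `c("S", "T", "Y")`); `NULL` disables filtering.
#' @param flank,pad Window parameters passed to [extract_window()].
#' @return A list with `sites` (tibble: `site_id`, `substrate`, `position`,
#'   `residue`, and `window` when `substrates` was given) and `links`
#'   (tibble: `site_id`, `kinase`), plus `n_rejected`.
#' @export
read_site_table <- function(path, substrates = NULL,
                            residue_filter = c("S", "T", "Y"),
                            flank = 7L, pad = "X") {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  need <- c("substrate", "position", "residue", "kinase")
  if (!all(need %in% names(raw))) {
    abort(sprintf("site table %s lacks column(s): %s", path,
                  paste(setdiff(need, names(raw)), collapse = ", ")),
          class = "kinsub_parse_error")
  }
  pos <- suppressWarnings(as.integer(raw$position))
  if (nrow(raw) > 0 && anyNA(pos)) {
    abort(sprintf("non-integer position at line %d of %s",
                  which(is.na(pos))[1] + 1L, path),
          class = "kinsub_parse_error")
  }
  raw$position <- pos
  n_rejected <- 0L
  if (!is.null(residue_filter) && nrow(raw) > 0) {
    keep <- raw$residue %in% residue_filter
    n_rejected <- sum(!keep)
    if (n_rejected > 0) {
      inform(sprintf("rejected %d row(s) with residue outside {%s}",
                     n_rejected, paste(residue_filter, collapse = ",")))
    }
    raw <- raw[keep, , drop = FALSE]
  }
  sites <- dplyr::distinct(raw, .data$substrate, .data$position,
                           .data$residue) |>
    dplyr::mutate(site_id = paste0(.data$substrate, "_", .data$position),
                  .before = 1)
  if (anyDuplicated(sites$site_id)) {
    dup <- sites$site_id[duplicated(sites$site_id)][1]
    abort(sprintf("conflicting residue annotations for site %s", dup),
          class = "kinsub_consistency_error")
  }
  # an empty/"-" kinase field marks a verified site with no annotated kinase
  links <- dplyr::distinct(raw, .data$substrate, .data$position,
                           .data$kinase) |>
    dplyr::filter(!is.na(.data$kinase), .data$kinase != "",
                  .data$kinase != "-") |>
    dplyr::transmute(site_id = paste0(.data$substrate, "_", .data$position),
                     kinase = .data$kinase)
  if (!is.null(substrates)) {
    sites <- attach_windows(sites, substrates, flank = flank, pad = pad)
  }
  list(sites = sites, links = links, n_rejected = n_rejected)
}

# check residue/sequence agreement and add the window column
attach_windows <- function(sites, substrates, flank = 7L, pad = "X") {
  idx <- match(sites$substrate, substrates$accession)
  if (anyNA(idx)) {
    abort(sprintf("substrate %s not found in sequence set",
                  sites$substrate[is.na(idx)][1]),
          class = "kinsub_reference_error")
  }
  seqs <- substrates$sequence[idx]
  at <- substr(seqs, sites$position, sites$position)
  off <- which(at != sites$residue)
  if (length(off) > 0) {
    i <- off[1]
    abort(sprintf(
      "residue mismatch for %s: annotated %s at %d but sequence has %s",
      sites$substrate[i], sites$residue[i], sites$position[i], at[i]),
      class = "kinsub_consistency_error")
  }
  sites$window <- extract_window(seqs, sites$position, flank = flank,
                                 pad = pad, accession = sites$substrate)
  sites
}

#' Write a phosphosite table
#'
#' Inverse of [read_site_table()]: one row per (site, kinase) link; sites
#' with no annotated kinase get a single row with `-` in the kinase column
#' so they survive a round trip.
#'
#' @param sites,links Tibbles as returned by [read_site_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, links, path) {
  out <- dplyr::left_join(sites, links, by = "site_id") |>
    dplyr::transmute(.data$substrate, .data$position, .data$residue,
                     kinase = dplyr::coalesce(.data$kinase, "-"))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a protein-protein interaction edge list
#'
#' Tab-separated `protein_a`, `protein_b`, `score` triples in the STRING
#' dialect.  Scores may be on the 0-1 decimal or 0-1000 integer scale
#' (auto-detected by the maximum value) and are normalized to 0-1 before the
#' confidence cutoff is applied.  Self-loops are dropped and the network is
#' made symmetric; duplicate orientations collapse to one undirected edge
#' (keeping the larger score).
#'
#' @param path Path to the edge list.  A header line is auto-detected.
#' @param cutoff Minimum combined confidence on the 0-1 scale
#'   (default 0.4, the STRING medium-confidence threshold).
#' @return A `ksr_ppi` object: list with `edges` (tibble `protein_a`,
#'   `protein_b`, `score`, undirected, filtered) and `neighbors` (named list
#'   of character vectors).
#' @export
read_ppi_edges <- function(path, cutoff = 0.4) {
  first <- readr::read_lines(path, n_max = 1)
  has_header <- length(first) == 1 &&
    is.na(suppressWarnings(as.numeric(strsplit(first, "\t")[[1]][3])))
  raw <- readr::read_tsv(
    path, col_names = c("protein_a", "protein_b", "score"),
    skip = if (has_header) 1L else 0L, show_col_types = FALSE,
    col_types = readr::cols("c", "c", "d"))
  ppi_from_edges(raw, cutoff = cutoff)
}

#' Build a PPI network from an in-memory edge tibble
#'
#' @param edges Tibble with `protein_a`, `protein_b`, `score`.
#' @inheritParams read_ppi_edges
#' @return A `ksr_ppi` object.
#' @export
ppi_from_edges <- function(edges, cutoff = 0.4) {
  s <- edges$score
  if (nrow(edges) > 0) {
    if (anyNA(s) || any(s < 0) || any(s > 1000)) {
      abort("PPI scores must be numbers in [0, 1] or [0, 1000]",
            class = "kinsub_parse_error")
    }
    if (max(s) > 1) s <- s / 1000
  }
  keep <- s >= cutoff & edges$protein_a != edges$protein_b
  a <- pmin(edges$protein_a[keep], edges$protein_b[keep])
  b <- pmax(edges$protein_a[keep], edges$protein_b[keep])
  ed <- tibble(protein_a = a, protein_b = b, score = s[keep]) |>
    dplyr::group_by(.data$protein_a, .data$protein_b) |>
    dplyr::summarise(score = max(.data$score), .groups = "drop")
  nb <- split(c(ed$protein_b, ed$protein_a), c(ed$protein_a, ed$protein_b))
  nb <- lapply(nb, function(x) sort(unique(x)))
  structure(list(edges = ed, neighbors = nb, cutoff = cutoff),
            class = "ksr_ppi")
}

#' @export
print.ksr_ppi <- function(x, ...) {
  cat(sprintf("<ksr_ppi> %d undirected edges, %d proteins, cutoff %.2f\n",
              nrow(x$edges), length(x$neighbors), x$cutoff))
  invisible(x)
}

ppi_neighbors <- function(ppi, accession) {
  ppi$neighbors[[accession]] %||% character(0)
}

#' Write a PPI edge list
#'
#' @param ppi A `ksr_ppi` object.
#' @param path Output path (tab-separated, 0-1 decimal scores, header).
#' @return `path`, invisibly.
#' @export
write_ppi_edges <- function(ppi, path) {
  readr::write_tsv(ppi$edges, path)
  invisible(path)
}

#' Build the site-by-kinase adjacency matrix
#'
#' Encodes the bipartite phosphosite-kinase network as a binary matrix `Y`
#' with `Y[i, j] = 1` when site `i` is annotated to kinase `j`; every other
#' (site, kinase) pair is 0.  Row and column order follow the input order.
#'
#' @param site_ids Ordered character vector of site ids.
#' @param kinases Ordered character vector of kinase names.
#' @param links Tibble with `site_id` and `kinase` columns; duplicates are
#'   idempotent.
#' @return Binary numeric matrix with `site_ids` rownames and `kinases`
#'   colnames.
#' @export
build_adjacency <- function(site_ids, kinases, links) {
  i <- match(links$site_id, site_ids)
  j <- match(links$kinase, kinases)
  if (anyNA(i)) {
    abort(sprintf("link references unknown site %s",
                  links$site_id[is.na(i)][1]),
          class = "kinsub_reference_error")
  }
  if (anyNA(j)) {
    abort(sprintf("link references unknown kinase %s",
                  links$kinase[is.na(j)][1]),
          class = "kinsub_reference_error")
  }
  y <- matrix(0, length(site_ids), length(kinases),
              dimnames = list(site_ids, kinases))
  y[cbind(i, j)] <- 1
  y
}

#' Kinases with enough positives to support a model
#'
#' @param adjacency Binary site-by-kinase matrix from [build_adjacency()].
#' @param min_positives Minimum number of annotated sites (default 15).
#' @return Character vector of kinase names in stable column order.
#' @export
select_model_kinases <- function(adjacency, min_positives = 15L) {
  colnames(adjacency)[colSums(adjacency) >= min_positives]
}

#' Binary label vector for one kinase
#'
#' Sites annotated to the kinase are positives; every other site in the
#' adjacency is a negative, regardless of residue type.
#'
#' @inheritParams select_model_kinases
#' @param kinase Kinase name (must be a column of `adjacency`).
#' @return Named numeric 0/1 vector over the adjacency's sites.
#' @export
label_vector <- function(adjacency, kinase) {
  if (!kinase %in% colnames(adjacency)) {
    abort(sprintf("kinase %s not in adjacency", kinase),
          class = "kinsub_reference_error")
  }
  adjacency[, kinase]
}

#' Read an accession-to-representative cluster map
#'
#' Consumes the output of an external redundancy-removal clustering (two
#' tab-separated columns: member accession, representative accession).
#'
#' @param path Path to the map; header auto-detected by the column names
#'   `member`/`representative`.
#' @return Named character vector mapping members to representatives.
#' @export
read_cluster_map <- function(path) {
  m <- readr::read_tsv(path, col_names = c("member", "representative"),
                       show_col_types = FALSE,
                       col_types = readr::cols("c", "c"))
  if (nrow(m) > 0 && m$member[1] == "member") m <- m[-1, , drop = FALSE]
  setNames(m$representative, m$member)
}
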