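#' Read and write annotated protein FASTA
#'
#' FASTA I/O for sequence record tables. The header convention is
#' `>id key=value key=value ...`; recognised keys are `species` (character),
#' `pfam_pf01212_present` and `pathogenic_host` (logical). `read_fasta()`
#' parses them into columns; unknown keys are ignored. Writing then reading a
#' record table is the identity.
#'
#' @param path file path.
#' @param records a tibble with at least `id` and `sequence`; optional
#'   `species`, `pfam_pf01212_present`, `pathogenic_host` columns become
#'   header key-value pairs.
#' @return `read_fasta()` returns a tibble with columns `id`, `species`,
#'   `sequence`, `length`, `pfam_pf01212_present`, `pathogenic_host`;
#'   `write_fasta()` returns `path` invisibly.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' fam <- generate_sequence_families(
#'   family_spec(2, 2, seed_length_mean = 40, seed_length_sd = 0, rng_seed = 1))
#' write_fasta(fam$records, tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  stop_if(!file.exists(path), "file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) {
    return(tibble::tibble(id = character(0), species = character(0),
                          sequence = character(0), length = integer(0),
                          pfam_pf01212_present = logical(0),
                          pathogenic_host = logical(0)))
  }
  headers <- names(aa)
  seqs <- as.character(aa)
  parse_header <- function(h, i) {
    parts <- strsplit(trimws(h), "\\s+")[[1]]
    stop_if(length(parts) == 0L || parts[1] == "",
            "record ", i, ": empty FASTA header")
    kv <- parts[-1][grepl("=", parts[-1], fixed = TRUE)]
    keys <- sub("=.*", "", kv)
    vals <- sub("^[^=]*=", "", kv)
    names(vals) <- keys
    list(id = parts[1], kv = vals)
  }
  parsed <- lapply(seq_along(headers), function(i) parse_header(headers[i], i))
  empty <- which(nchar(seqs) == 0L)
  stop_if(length(empty) > 0L,
          "empty sequence for record(s): ",
          paste(vapply(parsed[empty], `[[`, "", "id"), collapse = ", "))
  get_kv <- function(key, default) {
    vapply(parsed, function(p) unname(p$kv[key]) %||% default, default)
  }
  as_flag <- function(x) ifelse(is.na(x), NA, toupper(x) == "TRUE")
  tibble::tibble(
    id = vapply(parsed, `[[`, "", "id"),
    species = get_kv("species", NA_character_),
    sequence = unname(seqs),
    length = nchar(seqs),
    pfam_pf01212_present = as_flag(get_kv("pfam_pf01212_present",
                                          NA_character_)),
    pathogenic_host = as_flag(get_kv("pathogenic_host", NA_character_))
  )
}

#' @rdname read_fasta
#' @export
write_fasta <- function(records, path) {
  stop_if(is.null(records$id) || is.null(records$sequence),
          "'records' needs 'id' and 'sequence' columns")
  hdr <- records$id
  add_kv <- function(hdr, key) {
    if (!is.null(records[[key]])) {
      val <- records[[key]]
      ifelse(is.na(val), hdr, paste0(hdr, " ", key, "=", val))
    } else hdr
  }
  for (key in c("species", "pfam_pf01212_present", "pathogenic_host"))
    hdr <- add_kv(hdr, key)
  aa <- Biostrings::AAStringSet(setNames(records$sequence, hdr))
  Biostrings::writeXStringSet(aa, path, width = 70L)
  invisible(path)
}

#' Deduplicate records to one representative per species
#'
#' Reduces a redundant mined sequence set to a single representative per
#' species: the longest sequence, ties broken by lexicographically smallest
#' id (a deterministic rule; the original mining reduced >900 hits to 407
#' this way).
#'
#' @param records a record tibble with `species` annotations.
#' @return the deduplicated tibble, input order of first appearance retained.
#' @export
dedupe_by_species <- function(records) {
  missing <- is.na(records$species) | records$species == ""
  stop_if(any(missing),
          "records without species annotation: ",
          paste(records$id[missing], collapse = ", "))
  keep <- unlist(lapply(split(seq_len(nrow(records)), records$species),
                        function(idx) {
    sub <- records[idx, ]
    idx[order(-sub$length, sub$id)][1]
  }))
  records[sort(unname(keep)), ]
}

#' Hierarchical clustering of sequences on 1 - identity
#'
#' Agglomerative clustering of the distance view `1 - identity` using
#' `stats::hclust` (the canonical R implementation; complete linkage by
#' default, under which merge heights are non-decreasing).
#'
#' @param d an [identity_matrix()] (converted internally via [as_distance()])
#'   or a `dist` object.
#' @param linkage linkage method: `"complete"` (default), `"single"` or
#'   `"average"`.
#' @return an `hclust` tree (merge history plus heights).
#' @export
hierarchical_cluster <- function(d, linkage = c("complete", "single",
                                                "average")) {
  linkage <- match.arg(linkage)
  if (inherits(d, "identity_matrix")) d <- as_distance(d)
  stop_if(!inherits(d, "dist"), "'d' must be an identity matrix or dist")
  stop_if(anyNA(d), "distance matrix contains NA")
  hclust(d, method = linkage)
}

#' Cut a cluster tree into k groups or at a height
#'
#' Wraps `stats::cutree`; labels are relabelled to be contiguous `1..k` in
#' order of each cluster's first member.
#'
#' @param tree an `hclust` object from [hierarchical_cluster()].
#' @param k number of clusters (1..n), or
#' @param h height at which to cut (merges above `h` are undone).
#' @return named integer vector of cluster labels, attribute `k`.
#' @export
cut_tree <- function(tree, k = NULL, h = NULL) {
  stop_if(is.null(k) && is.null(h), "supply 'k' or 'h'")
  n <- length(tree$order)
  if (!is.null(k)) {
    stop_if(!is_count(k) || k > n, "'k' must be in 1..", n)
    raw <- cutree(tree, k = k)
  } else {
    stop_if(!is_number(h) || h < 0, "'h' must be >= 0")
    raw <- cutree(tree, h = h)
  }
  labels <- match(raw, unique(raw))
  names(labels) <- names(raw)
  structure(labels, k = length(unique(labels)))
}

#' Theoretical protein mass
#'
#' Sum of average residue masses plus one water, in kDa. Unknown residues
#' (`X`) use a generic 110 Da.
#'
#' @param sequence amino-acid string(s).
#' @return numeric vector of masses in kDa.
#' @export
theoretical_mass_kda <- function(sequence) {
  vapply(sequence, function(s) {
    chars <- strsplit(s, "")[[1]]
    m <- trp_constants$residue_masses[chars]
    stop_if(anyNA(m), "illegal residue in sequence: ",
            paste(unique(chars[is.na(m)]), collapse = ", "))
    (sum(m) + trp_constants$water_mass) / 1000
  }, numeric(1), USE.NAMES = FALSE)
}

#' Filter candidate sequences by rule set
#'
#' Applies length bounds, a theoretical-mass window and annotation-flag rules
#' in a fixed order; each discarded record carries the first rule it violated.
#' The mining pipeline used this to discard a 209-aa fragment and to keep
#' candidates near the ~50 kDa mass typical of tryptophanases.
#'
#' @param records record tibble.
#' @param rules a list with any of: `min_length`, `max_length` (aa),
#'   `mass_kda_range` (length-2 numeric), `require_flags` (character vector of
#'   logical columns that must be `TRUE`), `exclude_flags` (columns that must
#'   not be `TRUE`, e.g. `"pathogenic_host"`).
#' @return list with `kept` (tibble) and `discarded` (tibble with a `reason`
#'   column).
#' @examples
#' fam <- generate_sequence_families(
#'   family_spec(1, 3, seed_length_mean = 50, seed_length_sd = 0, rng_seed = 1))
#' filter_candidates(fam$records, list(min_length = 40))
#' @export
filter_candidates <- function(records, rules = list()) {
  reason <- rep(NA_character_, nrow(records))
  mark <- function(bad, why) ifelse(is.na(reason) & bad, why, reason)
  if (!is.null(rules$min_length))
    reason <- mark(records$length < rules$min_length, "length")
  if (!is.null(rules$max_length))
    reason <- mark(records$length > rules$max_length, "length")
  if (!is.null(rules$mass_kda_range)) {
    mass <- theoretical_mass_kda(records$sequence)
    reason <- mark(mass < rules$mass_kda_range[1] |
                     mass > rules$mass_kda_range[2], "mass")
  }
  for (flag in rules$require_flags %||% character(0)) {
    val <- records[[flag]]
    stop_if(is.null(val), "no such annotation column: ", flag)
    reason <- mark(!(val %in% TRUE), paste0("missing_", flag))
  }
  for (flag in rules$exclude_flags %||% character(0)) {
    val <- records[[flag]]
    stop_if(is.null(val), "no such annotation column: ", flag)
    reason <- mark(val %in% TRUE, flag)
  }
  discarded <- records[!is.na(reason), ]
  discarded$reason <- reason[!is.na(reason)]
  list(kept = records[is.na(reason), ], discarded = discarded)
}

#' Select one representative candidate per cluster
#'
#' Greedy diversity selection: clusters are visited in label order; within a
#' cluster only records passing the filter rules are admissible, and among
#' them the record maximising the mean distance (`1 - identity`) to all
#' already-selected candidates is chosen (ties by smallest id; for the first
#' selection every admissible record ties, so the smallest id wins). Clusters
#' with no admissible member yield no candidate and are reported.
#'
#' @param records record tibble.
#' @param assignment cluster labels from [cut_tree()], covering all records.
#' @param identity an [identity_matrix()] over the same ids.
#' @param rules filter rules as in [filter_candidates()].
#' @return list with `selected` (tibble `id`, `cluster`) and
#'   `empty_clusters` (integer labels with no admissible member).
#' @export
select_representatives <- function(records, assignment, identity,
                                   rules = list()) {
  stop_if(!all(records$id %in% names(assignment)),
          "assignment does not cover all records")
  dmat <- 1 - unclass(identity)
  admissible <- records$id[records$id %in%
                             filter_candidates(records, rules)$kept$id]
  selected <- character(0); clusters <- integer(0); empty <- integer(0)
  for (cl in sort(unique(assignment))) {
    members <- intersect(names(assignment)[assignment == cl], admissible)
    if (length(members) == 0L) { empty <- c(empty, cl); next }
    if (length(selected) == 0L) {
      pick <- sort(members)[1]
    } else {
      mean_d <- vapply(members,
                       function(id) mean(dmat[id, selected]), numeric(1))
      best <- members[mean_d == max(mean_d)]
      pick <- sort(best)[1]
    }
    selected <- c(selected, pick)
    clusters <- c(clusters, cl)
  }
  list(selected = tibble::tibble(id = selected, cluster = clusters),
       empty_clusters = empty)
}

#' Length summary of a sequence set
#'
#' @param records record tibble with a `length` column.
#' @return tibble with `n`, `mean_length`, `sd_length` (sample sd, 0 for a
#'   single record), `min_length`, `max_length`.
#' @export
cluster_summary <- function(records) {
  stop_if(nrow(records) < 1L, "need at least one record")
  len <- records$length
  tibble::tibble(
    n = length(len),
    mean_length = mean(len),
    sd_length = if (length(len) > 1L) sd(len) else 0,
    min_length = min(len),
    max_length = max(len)
  )
}
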