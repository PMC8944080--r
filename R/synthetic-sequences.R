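#' Specification for a synthetic protein-family population
#'
#' Parameters of the planted-cluster sequence generator. The defaults emulate
#' the bacterial tryptophanase population mined for the bioprospecting
#' pipeline: roughly 400 sequences in about 14 identity clusters with lengths
#' around 471 +/- 34 amino acids.
#'
#' @param n_families number of planted families (clusters).
#' @param members_per_family members per family; a single count or a
#'   length-2 range `c(min, max)` sampled uniformly per family.
#' @param seed_length_mean,seed_length_sd mean and standard deviation (aa) of
#'   the per-family seed-sequence length.
#' @param min_length hard lower clamp on generated lengths (aa).
#' @param within_family_identity target identity of each member to its family
#'   seed, in (0, 1].
#' @param between_family_identity_max maximum identity tolerated between
#'   families. Seeds are drawn independently and uniformly over the 20-letter
#'   alphabet, whose alignment-identity baseline is well below 0.3; requesting
#'   a smaller bound than the generator can guarantee is an error.
#' @param rng_seed integer seed; every random draw derives from it.
#' @return a `family_spec` list, validated.
#' @export
family_spec <- function(n_families,
                        members_per_family,
                        seed_length_mean = 471,
                        seed_length_sd = 34,
                        min_length = 30,
                        within_family_identity = 0.9,
                        between_family_identity_max = 0.5,
                        rng_seed = 1L) {
  stop_if(!is_count(n_families), "'n_families' must be a positive count")
  stop_if(!is.numeric(members_per_family) ||
            !length(members_per_family) %in% c(1L, 2L) ||
            any(members_per_family < 1),
          "'members_per_family' must be a count or a range c(min, max)")
  stop_if(!is_number(within_family_identity) ||
            within_family_identity <= 0 || within_family_identity > 1,
          "'within_family_identity' must be in (0, 1]")
  stop_if(!is_number(between_family_identity_max) ||
            between_family_identity_max < 0,
          "'between_family_identity_max' must be non-negative")
  stop_if(within_family_identity <= between_family_identity_max,
          "separation infeasible: within_family_identity (",
          within_family_identity, ") must exceed between_family_identity_max (",
          between_family_identity_max, ")")
  stop_if(between_family_identity_max < 0.3,
          "separation infeasible: independent random seeds cannot guarantee ",
          "between-family identity below 0.3")
  stop_if(!is_number(seed_length_mean) || seed_length_mean < 1,
          "'seed_length_mean' must be >= 1")
  stop_if(!is_number(seed_length_sd) || seed_length_sd < 0,
          "'seed_length_sd' must be >= 0")
  structure(list(n_families = as.integer(n_families),
                 members_per_family = as.integer(members_per_family),
                 seed_length_mean = seed_length_mean,
                 seed_length_sd = seed_length_sd,
                 min_length = as.integer(min_length),
                 within_family_identity = within_family_identity,
                 between_family_identity_max = between_family_identity_max,
                 rng_seed = as.integer(rng_seed)),
            class = "family_spec")
}

random_aa <- function(n) paste(sample(AA_ALPHABET, n, replace = TRUE),
                               collapse = "")

# Substitute a fraction of positions, always to a different residue, so the
# member's identity to the seed is exactly 1 - n_mut / length.
mutate_sequence <- function(seq, identity) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  n_mut <- round((1 - identity) * n)
  if (n_mut > 0) {
    pos <- sample.int(n, n_mut)
    for (p in pos) {
      chars[p] <- sample(setdiff(AA_ALPHABET, chars[p]), 1L)
    }
  }
  paste(chars, collapse = "")
}

#' Generate sequence families with planted cluster structure
#'
#' Each family derives from an independent random seed sequence drawn
#' uniformly over the 20 amino acids; members are substitution-only
#' point-mutated copies whose identity to the seed equals the requested
#' within-family identity (to rounding by sequence length). Two members of the
#' same family therefore share approximately `1 - 2*(1 - w)` identity, still
#' far above the random between-family baseline for any admissible
#' specification. Truth labels are returned so that cluster-recovery tests can
#' score the bioprospecting pipeline against ground truth.
#'
#' @param spec a [family_spec()].
#' @return A list with `records` (a tibble with columns `id`, `species`,
#'   `sequence`, `length`, `pfam_pf01212_present`, `pathogenic_host`) and
#'   `labels` (integer family id per record). The generating seed is kept in
#'   attribute `rng_seed`.
#' @examples
#' fam <- generate_sequence_families(
#'   family_spec(3, 4, seed_length_mean = 60, seed_length_sd = 5, rng_seed = 7))
#' table(fam$labels)
#' @export
generate_sequence_families <- function(spec) {
  stop_if(!inherits(spec, "family_spec"), "'spec' must be a family_spec")
  withr_seed <- spec$rng_seed
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(withr_seed)

  ids <- character(0); species <- character(0); seqs <- character(0)
  labels <- integer(0)
  for (f in seq_len(spec$n_families)) {
    len <- max(spec$min_length,
               round(rnorm(1, spec$seed_length_mean, spec$seed_length_sd)))
    seed_seq <- random_aa(len)
    n_mem <- if (length(spec$members_per_family) == 2L) {
      sample(seq.int(spec$members_per_family[1], spec$members_per_family[2]), 1L)
    } else spec$members_per_family
    for (m in seq_len(n_mem)) {
      ids <- c(ids, sprintf("fam%02d_m%02d", f, m))
      species <- c(species, sprintf("Synthbacter_f%02d_sp%02d", f, m))
      seqs <- c(seqs, mutate_sequence(seed_seq, spec$within_family_identity))
      labels <- c(labels, f)
    }
  }
  records <- tibble::tibble(
    id = ids,
    species = species,
    sequence = seqs,
    length = nchar(seqs),
    pfam_pf01212_present = TRUE,
    pathogenic_host = FALSE
  )
  structure(list(records = records, labels = labels), rng_seed = withr_seed)
}

# Save/restore the global RNG state so seeded generators do not perturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
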