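#' Point-mutation model for synthetic amplicon divergence
#'
#' Per-position substitution, insertion and deletion rates applied by
#' [mutate()]. Indel run lengths are geometric with success 1/2, capped at
#' `max_indel_len`, emulating the short-indel divergence typical of rRNA
#' amplicon data.
#'
#' @param sub_rate Probability that a position is substituted to a
#'   uniformly chosen different base.
#' @param ins_rate Probability that a random run is inserted after a
#'   position.
#' @param del_rate Probability that a deletion run starts at a position.
#' @param max_indel_len Cap on indel run length.
#' @param seed Default seed used by [mutate()] when none is given.
#' @return An object of class `mutation_model`.
#' @export
mutation_model <- function(sub_rate = 0, ins_rate = 0, del_rate = 0,
                           max_indel_len = 5L, seed = NULL) {
  stopifnot(sub_rate >= 0, ins_rate >= 0, del_rate >= 0,
            sub_rate + ins_rate + del_rate < 1, max_indel_len >= 1)
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate, max_indel_len = as.integer(max_indel_len),
                 seed = seed),
            class = "mutation_model")
}

#' Random nucleotide sequence
#'
#' I.i.d. uniform over A, C, G, T.
#'
#' @param length Positive sequence length.
#' @param seed Optional integer seed (uses the current RNG state if NULL).
#' @return A character scalar.
#' @export
random_sequence <- function(length, seed = NULL) {
  stopifnot(length >= 1)
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
}

# internal: geometric(1/2) run length capped at max_len
indel_lengths <- function(n, max_len) {
  pmin(stats::rgeom(n, 0.5) + 1L, max_len)
}

#' Mutate a sequence under a point-mutation model
#'
#' Each position is independently substituted with probability `sub_rate`
#' (always to a different base), starts a deletion run with probability
#' `del_rate`, and is followed by an inserted random run with probability
#' `ins_rate`. With all rates zero the sequence is returned unchanged.
#'
#' @param seq A single sequence.
#' @param model A [mutation_model()].
#' @param seed Integer seed; defaults to the model's seed, or the current
#'   RNG state when both are NULL.
#' @return The mutated sequence as a character scalar.
#' @export
mutate <- function(seq, model, seed = model$seed) {
  stopifnot(inherits(model, "mutation_model"))
  if (!is.null(seed)) set.seed(seed)
  chars <- strsplit(as_seq_string(seq), "")[[1L]]
  n <- length(chars)
  bases <- c("A", "C", "G", "T")

  # substitutions: pick one of the three other bases uniformly
  sub <- stats::runif(n) < model$sub_rate
  if (any(sub)) {
    offs <- sample.int(3L, sum(sub), replace = TRUE)
    cur <- match(chars[sub], bases)
    cur[is.na(cur)] <- sample.int(4L, sum(is.na(cur)), replace = TRUE)
    chars[sub] <- bases[((cur - 1L + offs) %% 4L) + 1L]
  }

  # deletions: runs starting at flagged positions (overlaps simply merge)
  del_start <- which(stats::runif(n) < model$del_rate)
  keep <- rep(TRUE, n)
  if (length(del_start) > 0L) {
    lens <- indel_lengths(length(del_start), model$max_indel_len)
    for (k in seq_along(del_start)) {
      i <- del_start[k]
      keep[i:min(i + lens[k] - 1L, n)] <- FALSE
    }
  }

  # insertions: random run after flagged positions
  ins_at <- which(stats::runif(n) < model$ins_rate)
  inserts <- character(n)
  if (length(ins_at) > 0L) {
    lens <- indel_lengths(length(ins_at), model$max_indel_len)
    inserts[ins_at] <- vapply(lens, function(L)
      paste(sample(bases, L, replace = TRUE), collapse = ""), character(1))
  }

  pieces <- paste0(ifelse(keep, chars, ""), inserts)
  out <- paste(pieces, collapse = "")
  if (nchar(out) == 0L)
    stop("mutation removed the entire sequence; rates too aggressive")
  out
}

# internal: derive a 32-bit substream seed from a master seed and indices
substream_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (i in idx) s <- (s * 48271 + i) %% 2147483647
  as.integer(s)
}

#' Generate synthetic amplicon families with genus-like labels
#'
#' Emulates the divergence structure of marker-gene amplicon data: one
#' random root sequence is diversified into `n_families` ancestors with the
#' `between_model`, and each ancestor into `members_per_family` members
#' with the `within_model`. Family ids serve as genus-like labels. Seeding
#' uses an explicit substream scheme so that adding a family does not
#' perturb earlier families.
#'
#' The default models place within-family identity around 95% and
#' between-family identity around 70-80%, the ballpark of genus-level 16S
#' divergence.
#'
#' @param n_families Number of families.
#' @param members_per_family Members per family.
#' @param length Root sequence length.
#' @param within_model,between_model [mutation_model()]s for member- and
#'   ancestor-level divergence.
#' @param seed Master integer seed.
#' @param distances If TRUE, also compute all-pairs alignment distances.
#' @param scoring An [nw_scoring()] object (used when `distances = TRUE`).
#' @return A list of class `synth_families` with `records` (data frame:
#'   `id`, `label`, `seq`) and, when requested, `dists` (data frame `a`,
#'   `b`, `d_a` over all unordered member pairs).
#' @export
make_families <- function(n_families, members_per_family, length = 150L,
                          within_model = mutation_model(
                            sub_rate = 0.04, ins_rate = 0.01, del_rate = 0.01),
                          between_model = mutation_model(
                            sub_rate = 0.22, ins_rate = 0.04, del_rate = 0.04),
                          seed = 1L, distances = FALSE,
                          scoring = nw_scoring()) {
  stopifnot(n_families >= 1, members_per_family >= 1)
  root <- random_sequence(length, seed = substream_seed(seed, 0L))
  ids <- character(0)
  labels <- character(0)
  seqs <- character(0)
  for (f in seq_len(n_families)) {
    anc <- mutate(root, between_model, seed = substream_seed(seed, f, 0L))
    for (m in seq_len(members_per_family)) {
      seqs <- c(seqs, mutate(anc, within_model,
                             seed = substream_seed(seed, f, m)))
      ids <- c(ids, sprintf("fam%02d_m%02d", f, m))
      labels <- c(labels, sprintf("fam%02d", f))
    }
  }
  out <- list(records = data.frame(id = ids, label = labels, seq = seqs,
                                   stringsAsFactors = FALSE))
  if (distances) {
    pr <- t(utils::combn(nrow(out$records), 2L))
    d <- alignment_distances(seqs, pr, scoring)
    out$dists <- data.frame(a = pr[, 1L], b = pr[, 2L], d_a = d$distance)
  }
  structure(out, class = "synth_families")
}

#' @export
print.synth_families <- function(x, ...) {
  cat(sprintf("synth_families: %d sequences in %d families\n",
              nrow(x$records), length(unique(x$records$label))))
  invisible(x)
}
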