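#' Configuration for the synthetic heterogeneous-network generator
#'
#' The generator plants a shared group partition across drugs, targets,
#' diseases and side-effects and samples every typed relation as a Bernoulli
#' stochastic block model: edge probability `p_in` when the two endpoints
#' share a group, `p_out` otherwise. Because all four node classes share the
#' partition, indirect drug-target routes (through shared diseases,
#' side-effects, or interacting drugs/targets) genuinely carry signal about
#' held-out drug-target interactions, which is the premise the full pipeline
#' is built on. Defaults are the package's standard study conditions.
#'
#' @param N_d,N_t,N_i,N_s node counts (drugs, targets, diseases, side-effects).
#' @param n_groups number of planted groups.
#' @param p_in,p_out within/between-group edge probabilities; scalars or
#'   length-6 vectors named after the relations
#'   (`DD`, `DT`, `DI`, `DS`, `TT`, `TI`).
#' @param fingerprint_len fingerprint length in bits.
#' @param flip_noise per-bit probability that a drug's fingerprint bit is
#'   flipped away from its group template.
#' @param seq_len_range length-2 integer range of target sequence lengths
#'   (residues).
#' @param motif_len length of the conserved per-group sequence motif
#'   (residues); 0 disables motif planting.
#' @param seed integer seed; drives four independent sub-streams (topology,
#'   fingerprints, sequences, noise) so a change in one component's draw
#'   count does not perturb the others.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(N_d = 60, N_t = 60, N_i = 30, N_s = 30,
                             n_groups = 2, p_in = 0.3, p_out = 0.02,
                             fingerprint_len = 128, flip_noise = 0.05,
                             seq_len_range = c(80L, 120L), motif_len = 15,
                             seed = 7) {
  cfg <- structure(list(N_d = N_d, N_t = N_t, N_i = N_i, N_s = N_s,
                        n_groups = n_groups,
                        p_in = expand_rates(p_in, "p_in"),
                        p_out = expand_rates(p_out, "p_out"),
                        fingerprint_len = fingerprint_len,
                        flip_noise = flip_noise,
                        seq_len_range = as.integer(seq_len_range),
                        motif_len = as.integer(motif_len),
                        seed = as.integer(seed)),
                   class = "synthetic_config")
  if (any(c(N_d, N_t, N_i, N_s, n_groups, fingerprint_len) <= 0))
    stop("synthetic_config: counts must be positive")
  if (any(cfg$p_out > cfg$p_in))
    stop("synthetic_config: p_out must not exceed p_in ",
         "(an anti-informative plant must be requested explicitly, not by accident)")
  if (any(cfg$p_in > 1) || any(cfg$p_out < 0))
    stop("synthetic_config: probabilities must lie in [0, 1]")
  if (cfg$seq_len_range[1] > cfg$seq_len_range[2])
    stop("synthetic_config: seq_len_range must be increasing")
  cfg
}

relation_names <- c("DD", "DT", "DI", "DS", "TT", "TI")

expand_rates <- function(p, what) {
  if (length(p) == 1L) p <- rep(p, 6L)
  if (length(p) != 6L) stop(what, " must be a scalar or length-6 vector")
  names(p) <- relation_names
  p
}

# Four decoupled RNG sub-streams derived from one seed.
substream_seed <- function(seed, k) (as.integer(seed) * 13L + k * 7919L) %% 2147483629L

sbm_block <- function(groups_row, groups_col, p_in, p_out,
                      symmetric = FALSE) {
  same <- outer(groups_row, groups_col, "==")
  P <- ifelse(same, p_in, p_out)
  A <- matrix(stats::rbinom(length(P), 1, as.vector(P)), nrow(P))
  if (symmetric) {
    A[lower.tri(A)] <- t(A)[lower.tri(A)]
    diag(A) <- 0
  }
  A
}

#' Generate a synthetic heterogeneous network with planted groups
#'
#' Assigns every node a group (balanced, round-robin) and samples the six
#' relations as stochastic block models sharing that partition. Drug-drug and
#' target-target relations are undirected with zero diagonal.
#'
#' @param cfg a [synthetic_config()].
#' @return A list with elements `network` (a [hetero_network()]) and `groups`
#'   (named list of integer group labels for the four node classes).
#' @export
generate_hetero <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(substream_seed(cfg$seed, 0L))
  grp <- function(n) rep_len(seq_len(cfg$n_groups), n)
  groups <- list(drug = grp(cfg$N_d), target = grp(cfg$N_t),
                 disease = grp(cfg$N_i), side_effect = grp(cfg$N_s))
  pi <- cfg$p_in; po <- cfg$p_out
  net <- hetero_network(
    drug_ids = sprintf("D%03d", seq_len(cfg$N_d)),
    target_ids = sprintf("T%03d", seq_len(cfg$N_t)),
    disease_ids = sprintf("I%03d", seq_len(cfg$N_i)),
    side_effect_ids = sprintf("S%03d", seq_len(cfg$N_s)),
    A_DD = sbm_block(groups$drug, groups$drug, pi["DD"], po["DD"], symmetric = TRUE),
    A_DT = sbm_block(groups$drug, groups$target, pi["DT"], po["DT"]),
    A_DI = sbm_block(groups$drug, groups$disease, pi["DI"], po["DI"]),
    A_DS = sbm_block(groups$drug, groups$side_effect, pi["DS"], po["DS"]),
    A_TT = sbm_block(groups$target, groups$target, pi["TT"], po["TT"], symmetric = TRUE),
    A_TI = sbm_block(groups$target, groups$disease, pi["TI"], po["TI"])
  )
  list(network = net, groups = groups)
}

#' Generate group-templated binary drug fingerprints
#'
#' Each group draws a Bernoulli(0.5) template bit pattern; each member copies
#' its group's template with independent per-bit flip noise, so within-group
#' Tanimoto similarity exceeds cross-group similarity in expectation.
#'
#' @param cfg a [synthetic_config()].
#' @param groups integer group labels for drugs (defaults to the labels
#'   [generate_hetero()] would assign).
#' @return Binary matrix `N_d x fingerprint_len` with drug ids as row names.
#' @export
generate_fingerprints <- function(cfg, groups = rep_len(seq_len(cfg$n_groups), cfg$N_d)) {
  stopifnot(inherits(cfg, "synthetic_config"), length(groups) == cfg$N_d)
  set.seed(substream_seed(cfg$seed, 1L))
  B <- cfg$fingerprint_len
  templates <- matrix(stats::rbinom(cfg$n_groups * B, 1, 0.5), cfg$n_groups, B)
  fp <- templates[groups, , drop = FALSE]
  flips <- matrix(stats::rbinom(length(fp), 1, cfg$flip_noise), nrow(fp))
  fp <- abs(fp - flips)
  rownames(fp) <- sprintf("D%03d", seq_len(cfg$N_d))
  fp
}

amino_acids <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Generate group-motif target sequences
#'
#' Each target gets a uniform-random amino-acid sequence (standard 20-letter
#' alphabet) of length drawn from `seq_len_range`, with a conserved per-group
#' motif of `motif_len` residues spliced in at a random position, so local
#' alignment scores separate groups.
#'
#' @inheritParams generate_fingerprints
#' @param groups integer group labels for targets.
#' @return Named character vector of sequences (target ids as names).
#' @export
generate_sequences <- function(cfg, groups = rep_len(seq_len(cfg$n_groups), cfg$N_t)) {
  stopifnot(inherits(cfg, "synthetic_config"), length(groups) == cfg$N_t)
  if (cfg$motif_len > cfg$seq_len_range[1])
    stop("generate_sequences: motif_len exceeds the minimum sequence length")
  set.seed(substream_seed(cfg$seed, 2L))
  motifs <- replicate(cfg$n_groups,
                      paste(sample(amino_acids, cfg$motif_len, replace = TRUE),
                            collapse = ""))
  seqs <- vapply(seq_len(cfg$N_t), function(i) {
    len <- sample(seq(cfg$seq_len_range[1], cfg$seq_len_range[2]), 1)
    s <- sample(amino_acids, len, replace = TRUE)
    if (cfg$motif_len > 0) {
      pos <- sample(seq_len(len - cfg$motif_len + 1L), 1)
      s[pos:(pos + cfg$motif_len - 1L)] <- strsplit(motifs[groups[i]], "")[[1]]
    }
    paste(s, collapse = "")
  }, character(1))
  names(seqs) <- sprintf("T%03d", seq_len(cfg$N_t))
  seqs
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper running [generate_hetero()], [generate_fingerprints()]
#' and [generate_sequences()] under one configuration.
#'
#' @param cfg a [synthetic_config()].
#' @return A list with `network`, `groups`, `fingerprints`, `sequences`, `cfg`.
#' @export
generate_synthetic_dataset <- function(cfg = synthetic_config()) {
  h <- generate_hetero(cfg)
  list(network = h$network, groups = h$groups,
       fingerprints = generate_fingerprints(cfg, h$groups$drug),
       sequences = generate_sequences(cfg, h$groups$target),
       cfg = cfg)
}

#' Write a synthetic dataset as a directory fixture
#'
#' Emits exactly the formats the readers consume: node lists and edge TSVs
#' ([write_hetero_network()]), a `fingerprints.tsv` (`drug_id<TAB>bitstring`),
#' a `targets.fasta`, and a `groups.tsv` with the ground-truth labels.
#'
#' @param ds result of [generate_synthetic_dataset()].
#' @param dir output directory.
#' @export
write_synthetic_dataset <- function(ds, dir) {
  write_hetero_network(ds$network, dir)
  write_fingerprints(ds$fingerprints, file.path(dir, "fingerprints.tsv"))
  write_sequences_fasta(ds$sequences, file.path(dir, "targets.fasta"))
  labels <- data.frame(
    node_id = c(ds$network$drug_ids, ds$network$target_ids,
                ds$network$disease_ids, ds$network$side_effect_ids),
    class = rep(c("drug", "target", "disease", "side_effect"),
                times = lengths(ds$groups)),
    group = unlist(ds$groups, use.names = FALSE))
  utils::write.table(labels, file.path(dir, "groups.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read / write drug fingerprints as TSV
#'
#' Format: headered TSV with columns `drug_id` and `bits` (a 0/1 string).
#' @param fp binary fingerprint matrix with drug ids as row names.
#' @param path file path.
#' @export
write_fingerprints <- function(fp, path) {
  df <- data.frame(drug_id = rownames(fp),
                   bits = apply(fp, 1, paste, collapse = ""))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fingerprints
#' @export
read_fingerprints <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  bits <- strsplit(df$bits, "")
  fp <- do.call(rbind, lapply(bits, as.numeric))
  rownames(fp) <- df$drug_id
  fp
}

#' Read / write target sequences as FASTA
#' @param seqs named character vector of amino-acid sequences.
#' @param path file path.
#' @export
write_sequences_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' @rdname write_sequences_fasta
#' @export
read_sequences_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}
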