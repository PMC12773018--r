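# Seeded generators that emulate the statistical structure of each task so
# the full pipeline is testable with no downloads. These are planted-signal
# stand-ins: they reproduce class imbalance, label rules and signal
# geometry, not real biological sequence statistics.

# class-imbalance presets mirroring the composition of the curated corpora
# (positive fractions), for realistic metric behavior
TABLE2_BALANCE <- c(hemolysis = 0.78, non_fouling = 0.79,
                    toxicity = 0.50, solubility = 0.48)

#' Configuration for the synthetic generators
#'
#' @param n Number of records.
#' @param length_range Residue length range (min, max).
#' @param class_balance Positive fraction in (0, 1).
#' @param effect_size Signal weight; 0 makes labels independent of the
#'   sequence.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed Integer seed; the same config always yields the identical
#'   corpus.
#' @return A `synth_config`.
#' @export
synth_config <- function(n = 1000, length_range = c(8, 20),
                         class_balance = 0.5, effect_size = 3,
                         noise_sd = 0.5, seed = 1) {
  stopifnot(n >= 1, length_range[1] >= 2,
            length_range[1] <= length_range[2],
            class_balance > 0, class_balance < 1, noise_sd >= 0)
  structure(list(n = n, length_range = length_range,
                 class_balance = class_balance, effect_size = effect_size,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synth_config")
}

.rand_seqs <- function(n, length_range) {
  lens <- sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
  vapply(lens, function(L)
    paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = ""),
    character(1))
}

.seq_score <- function(seqs, rule) {
  if (rule == "charge") {
    vapply(seqs, function(s)
      sum(.residue_charge7[strsplit(s, "")[[1]]]), numeric(1))
  } else {
    vapply(seqs, function(s)
      mean(KD_HYDROPATHY[strsplit(s, "")[[1]]]), numeric(1))
  }
}

SYNTH_MOTIF <- "KWKF"
SYNTH_MOTIF_POS <- 3L

#' Generate a planted-signal binary property corpus
#'
#' `charge` and `hydropathy` rules: a latent logistic variable
#' `effect_size * standardized_score + noise` is thresholded at the
#' quantile matching `class_balance`, so the achieved positive fraction
#' matches the requested balance and `effect_size = 0` makes labels
#' independent of the sequence. The `motif` rule instead plants a fixed
#' 4-mer at a fixed position in positives and at a random other position
#' in negatives (labels flipped with probability
#' `plogis(-effect_size)`), so composition-blind pooled heads see nothing
#' while positional heads can exceed them.
#'
#' @param cfg A `synth_config`.
#' @param rule `"charge"`, `"hydropathy"` or `"motif"`.
#' @param task_name Property name for the emitted dataset.
#' @return A `property_dataset` (AA modality, binary task).
#' @export
gen_binary_corpus <- function(cfg, rule = c("charge", "hydropathy",
                                            "motif"),
                              task_name = "hemolysis") {
  rule <- match.arg(rule)
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  seqs <- .rand_seqs(cfg$n, cfg$length_range)
  if (rule == "motif") {
    y <- rbinom(cfg$n, 1, cfg$class_balance)
    k <- nchar(SYNTH_MOTIF)
    for (i in seq_len(cfg$n)) {
      L <- nchar(seqs[i])
      pos <- if (y[i] == 1) SYNTH_MOTIF_POS else {
        cand <- setdiff(seq_len(L - k + 1), SYNTH_MOTIF_POS)
        if (length(cand) == 0) SYNTH_MOTIF_POS else
          cand[sample.int(length(cand), 1)]
      }
      substr(seqs[i], pos, pos + k - 1) <- SYNTH_MOTIF
    }
    flip <- rbinom(cfg$n, 1, plogis(-cfg$effect_size))
    y <- ifelse(flip == 1, 1 - y, y)
  } else {
    s <- .seq_score(seqs, rule)
    s <- (s - mean(s)) / max(sd(s), 1e-12)
    u <- cfg$effect_size * s + rnorm(cfg$n, sd = max(cfg$noise_sd, 1e-9))
    y <- as.numeric(u > quantile(u, 1 - cfg$class_balance))
  }
  task <- property_task(task_name, "binary", modalities = c("AA", "SMILES"),
                        positive_meaning = paste("synthetic", rule,
                                                 "positive"))
  records <- lapply(seq_len(cfg$n), function(i)
    peptide_record(sprintf("syn%05d", i), "AA", seqs[i],
                   labels = stats::setNames(list(y[i]), task_name),
                   source = paste0("synthetic:", rule)))
  property_dataset(task, records)
}

#' Convert an AA dataset to its SMILES twin
#'
#' Same ids, labels and order; payloads run through
#' [sequence_to_smiles()], so cluster-based split assignments can be
#' propagated across modalities.
#'
#' @param ds An AA `property_dataset`.
#' @return A SMILES `property_dataset`.
#' @export
convert_dataset_to_smiles <- function(ds) {
  task <- ds$task
  if (!("SMILES" %in% task$modalities))
    task$modalities <- c(task$modalities, "SMILES")
  records <- lapply(ds$records, function(r) {
    peptide_record(r$id, "SMILES", sequence_to_smiles(r$payload),
                   labels = r$labels, source = paste0(r$source, ":smi"))
  })
  property_dataset(task, records)
}

#' Generate a synthetic permeability corpus
#'
#' Continuous log Pexp values are drawn from a two-component normal
#' mixture straddling the -6.0 labeling boundary; binary labels apply the
#' rule `log Pexp >= -6.0` is high permeability. Both the continuous and
#' the derived binary task are emitted.
#'
#' @param cfg A `synth_config`; `class_balance` is the weight of the
#'   high-permeability mixture component.
#' @param means,sds Mixture component means/sds (low, high), defaults
#'   `(-8, -5)` and `(0.8, 0.8)`.
#' @return List: `continuous` (regression dataset), `binary` (thresholded
#'   dataset), `threshold` (-6).
#' @export
gen_permeability_corpus <- function(cfg, means = c(-8, -5),
                                    sds = c(0.8, 0.8)) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  seqs <- .rand_seqs(cfg$n, cfg$length_range)
  comp <- rbinom(cfg$n, 1, cfg$class_balance) + 1 # 1 = low, 2 = high
  logp <- rnorm(cfg$n, mean = means[comp], sd = sds[comp])
  y <- as.numeric(logp >= -6.0)
  ids <- sprintf("perm%05d", seq_len(cfg$n))
  task_c <- property_task("permeability_pampa", "regression",
                          modalities = c("AA", "SMILES"),
                          threshold = -6.0)
  task_b <- property_task("permeability_penetrance", "binary",
                          modalities = c("AA", "SMILES"),
                          positive_meaning = "high permeability",
                          threshold = -6.0)
  rec_c <- lapply(seq_len(cfg$n), function(i)
    peptide_record(ids[i], "AA", seqs[i],
                   labels = list(permeability_pampa = logp[i]),
                   source = "synthetic:permeability"))
  rec_b <- lapply(seq_len(cfg$n), function(i)
    peptide_record(ids[i], "AA", seqs[i],
                   labels = list(permeability_penetrance = y[i]),
                   source = "synthetic:permeability"))
  list(continuous = property_dataset(task_c, rec_c),
       binary = property_dataset(task_b, rec_b), threshold = -6.0)
}

# deterministic part of the planted affinity function: position-dependent
# residue compatibility (hydropathy product at a fixed offset), rescaled
# into the unified [4, 12] band
.affinity_true_score <- function(pep, prot, offset = 3) {
  hp <- KD_HYDROPATHY[strsplit(pep, "")[[1]]] / 4.5
  hq <- KD_HYDROPATHY[strsplit(prot, "")[[1]]] / 4.5
  i <- seq_along(hp)
  j <- i + offset
  keep <- j <= length(hq)
  raw <- sum(hp[keep] * hq[j[keep]]) / sqrt(max(sum(keep), 1))
  8 + 3 * pmin(pmax(raw * 2, -4 / 3), 4 / 3)
}

#' Generate synthetic peptide-protein affinity pairs
#'
#' Random peptides and proteins; the true score is a position-weighted
#' residue-compatibility sum (peptide residue i against protein residue
#' i + offset), rescaled into the unified [4, 12] band, plus Gaussian
#' noise. Classes are derived from the final score by [affinity_class()].
#' With `noise_sd = 0` the generator formula reproduces every score
#' exactly.
#'
#' @param cfg A `synth_config` (`length_range` applies to peptides).
#' @param protein_length_range Protein length range (default 30-60).
#' @param offset Positional offset of the compatibility interaction.
#' @return List of `affinity_pair`s.
#' @export
gen_affinity_pairs <- function(cfg, protein_length_range = c(30, 60),
                               offset = 3) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  peps <- .rand_seqs(cfg$n, cfg$length_range)
  prots <- .rand_seqs(cfg$n, protein_length_range)
  noise <- rnorm(cfg$n, sd = cfg$noise_sd)
  lapply(seq_len(cfg$n), function(i) {
    score <- .affinity_true_score(peps[i], prots[i], offset) + noise[i]
    rec <- peptide_record(sprintf("ap%05d", i), "AA", peps[i],
                          labels = list(binding_affinity = score),
                          source = "synthetic:affinity")
    affinity_pair(rec, prots[i], score)
  })
}

#' Generate paired synthetic stability and half-life corpora
#'
#' A latent stability signal s (standardized hydropathy) drives both
#' tasks: the stability corpus exposes `s + noise` at large n, and
#' half-life hours are `exp(a*s + b + noise)` for a sparse subset of the
#' same peptides (shared ids), so `log(1 + hours)` correlates with s and
#' stability pretraining transfers.
#'
#' @param cfg A `synth_config`; `cfg$n` is the half-life corpus size and
#'   is capped at 500 to mimic the sparse regime.
#' @param n_pretrain Stability corpus size (default 2000).
#' @param a,b Log-linear map from stability to hours.
#' @param stability_noise_sd Noise on the stability labels.
#' @return List: `stability` (`property_dataset`), `halflife` (list of
#'   `halflife_record`s).
#' @export
gen_halflife <- function(cfg, n_pretrain = 2000, a = 0.8, b = 1.0,
                         stability_noise_sd = 0.3) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$n > 500)
    stop("half-life corpus is capped at n = 500 (sparse regime)")
  set.seed(cfg$seed)
  seqs <- .rand_seqs(n_pretrain, cfg$length_range)
  s <- vapply(seqs, function(x)
    mean(KD_HYDROPATHY[strsplit(x, "")[[1]]]), numeric(1))
  s <- (s - mean(s)) / max(sd(s), 1e-12)
  stab <- s + rnorm(n_pretrain, sd = stability_noise_sd)
  ids <- sprintf("hl%05d", seq_len(n_pretrain))
  task <- property_task("stability", "regression")
  stab_rec <- lapply(seq_len(n_pretrain), function(i)
    peptide_record(ids[i], "AA", seqs[i],
                   labels = list(stability = stab[i]),
                   source = "synthetic:stability"))
  hours <- exp(a * s[seq_len(cfg$n)] + b +
                 rnorm(cfg$n, sd = max(cfg$noise_sd, 1e-9)))
  hl <- lapply(seq_len(cfg$n), function(i)
    halflife_record(
      peptide_record(ids[i], "AA", seqs[i],
                     labels = list(half_life = hours[i]),
                     source = "synthetic:halflife"),
      hours[i]))
  list(stability = property_dataset(task, stab_rec), halflife = hl)
}
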