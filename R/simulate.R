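#' Synthetic 25-region membrane topology
#'
#' Builds a transporter-like topology with intracellular N- and C-termini,
#' 12 transmembrane segments, 6 extracellular and 5 intracellular loops
#' (25 regions in total), in the alternating order a 12-TM transporter
#' imposes. For the default L = 557 the layout mimics a carnitine
#' transporter-like architecture (a long first extracellular loop, a long
#' third intracellular loop, and two very short extracellular loops of 4
#' and 3 residues); other lengths scale the region sizes proportionally
#' with a minimum of one residue per region.
#'
#' @param L protein length (>= 25).
#' @return a `topology_map`.
#' @export
synthetic_topology <- function(L = 557) {
  stopifnot(L >= 25)
  name <- c("N-term",
            "TM1", "EL1", "TM2", "IL1", "TM3", "EL2", "TM4", "IL2",
            "TM5", "EL3", "TM6", "IL3", "TM7", "EL4", "TM8", "IL4",
            "TM9", "EL5", "TM10", "IL5", "TM11", "EL6", "TM12",
            "C-term")
  cls <- c("N-term",
           "TM", "EL", "TM", "IL", "TM", "EL", "TM", "IL",
           "TM", "EL", "TM", "IL", "TM", "EL", "TM", "IL",
           "TM", "EL", "TM", "IL", "TM", "EL", "TM",
           "C-term")
  base <- c(45,
            21, 70, 21, 10, 21, 4, 21, 12,
            21, 9, 21, 62, 21, 10, 21, 11,
            21, 3, 21, 14, 21, 12, 21,
            43)  # sums to 557
  len <- pmax(1L, floor(base * L / sum(base)))
  # largest-remainder correction so lengths sum exactly to L
  while (sum(len) < L) {
    rem <- base * L / sum(base) - len
    i <- which.max(rem)
    len[i] <- len[i] + 1L
  }
  while (sum(len) > L) {
    i <- which.max(len)
    len[i] <- len[i] - 1L
  }
  end <- cumsum(len)
  topology_map(data.frame(name = name, class = cls,
                          start = c(1L, utils::head(end, -1) + 1L),
                          end = end, stringsAsFactors = FALSE))
}

#' Random protein sequence matched to a topology
#'
#' Residues are drawn per region class: transmembrane segments are
#' enriched in hydrophobic residues, loops in polar/charged ones -- enough
#' realism for topology-aware features without pretending to be a real
#' sequence.
#'
#' @param topo a `topology_map`.
#' @param id sequence identifier.
#' @return a [protein_sequence()]. Uses the current RNG state.
#' @export
random_protein <- function(topo, id = "synthetic") {
  hydro <- pmax(aa_hydropathy + 5, 0.5)
  polar <- pmax(5 - aa_hydropathy, 0.5)
  residues <- unlist(lapply(seq_len(nrow(topo)), function(i) {
    n <- topo$end[i] - topo$start[i] + 1L
    w <- if (topo$class[i] == "TM") hydro else polar
    sample(aa_alphabet, n, replace = TRUE, prob = w / sum(w))
  }))
  protein_sequence(residues, id = id)
}

#' Synthetic helical coordinate model
#'
#' C-alpha coordinates along an ideal alpha helix (1.5 A rise, 100 degree
#' turn, 2.3 A radius) -- a regular geometry convenient for unit-testing
#' the structure feature extractors against brute force.
#'
#' @param L number of residues.
#' @param plddt optional per-residue confidence; defaults to draws in
#'   70-95 using the current RNG state.
#' @return a [structure_model()].
#' @export
synthetic_helix <- function(L, plddt = NULL) {
  t <- seq_len(L)
  ang <- t * 100 * pi / 180
  coords <- cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * t)
  if (is.null(plddt)) plddt <- stats::runif(L, 70, 95)
  structure_model(coords, plddt)
}

#' Synthetic globular coordinate model
#'
#' A compact chain: a 3.8 A-step random walk confined to a sphere whose
#' radius matches a typical protein packing density, giving core residues
#' high contact numbers and surface residues low ones. This variation in
#' burial is what the study generator needs from a structure (an ideal
#' helix gives every interior residue the same contact count); it still
#' does not emulate a real transporter fold. Uses the current RNG state.
#'
#' @param L number of residues.
#' @param plddt optional per-residue confidence; defaults to draws in
#'   70-95.
#' @return a [structure_model()].
#' @export
synthetic_globule <- function(L, plddt = NULL) {
  radius <- 3.2 * L^(1 / 3)   # ~134 A^3 per residue packing
  coords <- matrix(0, nrow = L, ncol = 3)
  for (i in seq_len(L)[-1]) {
    repeat {
      step <- stats::rnorm(3)
      cand <- coords[i - 1, ] + 3.8 * step / sqrt(sum(step^2))
      if (sum(cand^2) <= radius^2) break
    }
    coords[i, ] <- cand
  }
  if (is.null(plddt)) plddt <- stats::runif(L, 70, 95)
  structure_model(coords, plddt)
}

#' Default configuration of the synthetic characterization study
#'
#' The generator's defaults define the study conditions: 150 variants over
#' a 557-residue transporter (the characterized-set size and protein
#' length of the real study), ~25% LOF prevalence, three biological
#' replicates of three technical wells, replicate noise on the
#' percent-of-WT scale, three-class localization derived from the same
#' latent liability as function with 10% label noise, eight
#' ancestry-style groups with a LOF-enriched clinical analogue, and rare
#' allele frequencies (all below 0.01).
#'
#' @param ... overrides of the listed defaults.
#' @return config list.
#' @export
study_config <- function(...) {
  cfg <- list(
    L = 557, n_variants = 150,
    lof_target = 0.25,          # calibrated LOF prevalence
    bio_reps = 3, tech_reps = 3,
    noise_bio_sd = 8,           # biological replicate SD, %WT units
    noise_tech_sd = 4,          # technical well SD, %WT units
    ev_counts = 50, wt_counts = 550,   # counts/ug: background and WT signal
    loc_thresholds = c(intracellular = 30, membrane = 62),  # %WT
    label_noise = 0.1,
    groups = c("Shared", "Random", "African", "EastAsian", "European",
               "Latino", "SouthAsian", "Clinical"),
    clinical_n = 10, clinical_lof_weight = 8,
    populations = c("African", "EastAsian", "European", "Latino",
                    "SouthAsian"),
    af_mean = 2e-4, af_cap = 0.01,
    score_tables = c("vae_score", "potts_score", "plm_score"),
    score_noise_sd = 0.15,
    # True coefficients on the 0-1 scaled feature columns: a sparse,
    # detectable truth (transmembrane location, substitution severity,
    # pore proximity, proline introduction) at n = 150. Note
    # contact_number/rel_burial are affinely identical after scaling, so
    # a planted effect on either would not be identifiable.
    beta = c(class_TM = 2.0, blosum62 = -2.5, axis_dist = -2.0,
             proline_introduced = 1.5)
  )
  over <- list(...)
  cfg[names(over)] <- over
  if (cfg$lof_target <= 0 || cfg$lof_target >= 1) {
    stop("degenerate config: LOF prevalence must be strictly in (0, 1)",
         call. = FALSE)
  }
  cfg
}

#' Simulate a complete synthetic characterization study
#'
#' Generates a full study with known ground truth: a topology-matched
#' random protein and helix structure; a latent liability
#' `l = b0 + x' beta` over the 0-1 scaled sequence+structure features of
#' every possible missense variant, with the intercept calibrated on the
#' full enumeration so that `120 * plogis(-l) < 20` (true LOF) holds for
#' the target fraction of variants; `n_variants` study variants drawn
#' uniformly; raw uptake replicates produced by inverting the
#' normalization formula around batch WT/EV controls plus Gaussian
#' replicate noise; localization classes cut from the true function with
#' label noise; a LOF-enriched clinical-analogue group; rare allele
#' frequencies; and external-predictor-style score tables generated as
#' noisy transforms of the same liability. The 120-logistic scale keeps
#' true function in a realistic range with tails slightly outside
#' 0-100%.
#'
#' @param config a [study_config()].
#' @param seed master seed; all stage seeds derive from it.
#' @return list of class `synthetic_study`; see the fields in the source
#'   and the methods vignette.
#' @export
simulate_study <- function(config = study_config(), seed = 1) {
  cfg <- config
  set.seed(derive_seed(seed, 1L))
  topo <- synthetic_topology(cfg$L)
  seq <- random_protein(topo, id = sprintf("synthetic_L%d", cfg$L))
  structure <- synthetic_globule(cfg$L)

  # liability over the full enumeration (so the study sample is unbiased)
  all_var <- enumerate_missense(seq)
  x_raw_all <- cbind(
    sequence_features(all_var, seq, topo),
    structure_features(all_var, structure)
  )
  scaling <- fit_feature_scaling(x_raw_all)
  x_all <- scale_features(x_raw_all, scaling)
  beta <- cfg$beta
  missing_beta <- setdiff(names(beta), colnames(x_all))
  if (length(missing_beta) > 0L) {
    stop("true beta names absent from feature matrix: ",
         paste(missing_beta, collapse = ", "), call. = FALSE)
  }
  xb <- drop(x_all[, names(beta), drop = FALSE] %*% beta)
  # true LOF <=> 120*plogis(-l) < 20 <=> l > log(5); calibrate intercept
  b0 <- log(5) - stats::quantile(xb, 1 - cfg$lof_target, names = FALSE)
  liability <- b0 + xb
  true_fn_all <- 120 * stats::plogis(-liability)

  set.seed(derive_seed(seed, 2L))
  pick <- sort(sample(nrow(all_var), cfg$n_variants))
  variants <- all_var[pick, , drop = FALSE]
  rownames(variants) <- NULL
  variants$true_fn <- true_fn_all[pick]
  variants$true_lof <- variants$true_fn < 20

  # groups: clinical analogue enriched for LOF, others uniform
  set.seed(derive_seed(seed, 3L))
  n <- cfg$n_variants
  w <- ifelse(variants$true_lof, cfg$clinical_lof_weight, 1)
  clin_n <- min(cfg$clinical_n, n)
  clin <- sample(n, clin_n, prob = w)
  group <- character(n)
  group[clin] <- "Clinical"
  others <- setdiff(cfg$groups, "Clinical")
  group[-clin] <- sample(rep_len(others, n - clin_n))
  variants$group <- group

  # localization from the same latent function plus label noise
  set.seed(derive_seed(seed, 4L))
  loc <- ifelse(variants$true_fn < cfg$loc_thresholds["intracellular"],
                "intracellular",
                ifelse(variants$true_fn > cfg$loc_thresholds["membrane"],
                       "membrane", "mixed"))
  flip <- stats::runif(n) < cfg$label_noise
  loc[flip] <- vapply(loc[flip], function(cl) {
    sample(setdiff(c("membrane", "mixed", "intracellular"), cl), 1)
  }, character(1))
  variants$localization <- loc

  # raw assay wells: invert the normalization formula around controls
  set.seed(derive_seed(seed, 5L))
  span <- cfg$wt_counts - cfg$ev_counts
  per_batch <- 30L
  # random plate layout: batch must not track position (the sampled
  # variants are position-sorted), or shared-control noise would confound
  # batch effects with positional features
  batch_of <- sample(ceiling(seq_len(n) / per_batch))
  well_rows <- function(lab, batch, fn_true) {
    rows <- list()
    for (b in seq_len(cfg$bio_reps)) {
      bio_off <- stats::rnorm(1, 0, cfg$noise_bio_sd)
      tech <- stats::rnorm(cfg$tech_reps, 0, cfg$noise_tech_sd)
      fn_obs <- fn_true + bio_off + tech
      rows[[b]] <- data.frame(
        variant = lab, batch = batch, bio_rep = b,
        tech_rep = seq_len(cfg$tech_reps),
        uptake_counts_per_ug = cfg$ev_counts + span * fn_obs / 100,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }
  assay <- list()
  for (bt in unique(batch_of)) {
    assay[[length(assay) + 1L]] <- well_rows("WT", bt, 100)
    assay[[length(assay) + 1L]] <- well_rows("EV", bt, 0)
    for (i in which(batch_of == bt)) {
      assay[[length(assay) + 1L]] <-
        well_rows(variants$label[i], bt, variants$true_fn[i])
    }
  }
  assay <- do.call(rbind, assay)

  # characterized table via the real pipeline
  characterized <- characterize_assay(assay, n_tests = n)
  characterized <- characterized[match(variants$label,
                                       characterized$label), ]
  rownames(characterized) <- NULL
  characterized$localization <- variants$localization
  characterized$group <- variants$group

  # rare allele frequencies; population presence follows the group label
  set.seed(derive_seed(seed, 6L))
  draw_af <- function() {
    repeat {
      af <- stats::rexp(1, rate = 1 / cfg$af_mean)
      if (af < cfg$af_cap) return(af)
    }
  }
  af_rows <- list()
  for (i in seq_len(n)) {
    pops <- switch(variants$group[i],
      Shared = sample(cfg$populations, sample(2:4, 1)),
      Random = ,
      Clinical = sample(cfg$populations, sample(1:3, 1)),
      variants$group[i]  # population-exclusive groups
    )
    pops <- intersect(pops, cfg$populations)
    for (p in pops) {
      af_rows[[length(af_rows) + 1L]] <-
        data.frame(variant = variants$label[i], population = p,
                   allele_frequency = draw_af(), stringsAsFactors = FALSE)
    }
  }
  afs <- do.call(rbind, af_rows)

  # external-predictor-style score tables from the same liability
  set.seed(derive_seed(seed, 7L))
  score_tables <- lapply(cfg$score_tables, function(nm) {
    data.frame(variant = variants$label,
               score = stats::plogis(-(b0 + xb[pick])) +
                 stats::rnorm(n, 0, cfg$score_noise_sd),
               stringsAsFactors = FALSE)
  })
  names(score_tables) <- cfg$score_tables

  features <- cbind(x_raw_all[pick, , drop = FALSE],
                    prediction_features(variants, score_tables))
  rownames(features) <- variants$label

  truth <- list(beta = beta, intercept = b0,
                noise_bio_sd = cfg$noise_bio_sd,
                noise_tech_sd = cfg$noise_tech_sd,
                label_noise = cfg$label_noise,
                lof_target = cfg$lof_target,
                feature_names = colnames(x_raw_all), seed = seed)

  structure(list(seq = seq, topo = topo, structure = structure,
                 variants = variants, assay = assay,
                 characterized = characterized, features = features,
                 score_tables = score_tables, afs = afs,
                 truth = truth, config = cfg, seed = seed),
            class = "synthetic_study")
}

#' Ground-truth parameters of a synthetic study
#'
#' @param study a [simulate_study()] result.
#' @return the generating parameters (true coefficients, intercept, noise
#'   SDs, label-noise rate, target prevalence, seed).
#' @export
truth_report <- function(study) {
  stopifnot(inherits(study, "synthetic_study"))
  study$truth
}

#' Write a synthetic study to disk in the pipeline's input formats
#'
#' Emits every file the real pipeline consumes: FASTA sequence, topology
#' TSV, raw-assay TSV, characterized-variant TSV, per-predictor score
#' TSVs and the allele-frequency TSV.
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if absent).
#' @return invisibly, the vector of files written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  fa <- file.path(dir, "sequence.fasta")
  writeLines(c(paste0(">", study$seq$id),
               paste(study$seq$residues, collapse = "")), fa)
  paths <- c(paths, fa)
  paths <- c(paths, write_tsv(as.data.frame(study$topo),
                              file.path(dir, "topology.tsv")))
  paths <- c(paths, write_tsv(study$assay, file.path(dir, "assay.tsv")))
  chr <- study$characterized
  names(chr)[names(chr) == "label"] <- "variant"
  paths <- c(paths, write_tsv(chr, file.path(dir, "characterized.tsv")))
  for (nm in names(study$score_tables)) {
    paths <- c(paths, write_tsv(study$score_tables[[nm]],
                                file.path(dir, paste0(nm, ".tsv"))))
  }
  paths <- c(paths, write_tsv(study$afs,
                              file.path(dir, "allele_frequencies.tsv")))
  invisible(paths)
}
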