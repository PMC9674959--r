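#' Sequence- and topology-based features for missense variants
#'
#' The sequence feature set describes the amino-acid change and its
#' position in the transporter: raw residue position; indicator features
#' for the five topological region classes (N-term, TM, EL, IL, C-term)
#' and for each individual region of the map; the Kyte-Doolittle
#' hydropathy change (alt minus ref); the net side-chain charge change at
#' pH 7; the residue volume change; the BLOSUM62 substitution score; and
#' indicators for introducing a proline or removing a glycine. Features
#' depend only on (pos, ref, alt, topology) -- never on assay results.
#'
#' @param variants validated variant data.frame (`label`, `pos`, `ref`,
#'   `alt`).
#' @param seq a [protein_sequence()].
#' @param topo a `topology_map`.
#' @return numeric matrix, rows named by variant label.
#' @export
sequence_features <- function(variants, seq, topo) {
  validate_against_sequence(variants, seq)
  reg <- region_of(variants$pos, topo)
  classes <- c("N-term", "TM", "EL", "IL", "C-term")
  cls_ind <- sapply(classes, function(cl) as.numeric(reg$class == cl))
  colnames(cls_ind) <- paste0("class_", sub("-", "", classes))
  reg_ind <- sapply(topo$name, function(nm) as.numeric(reg$name == nm))
  colnames(reg_ind) <- paste0("region_", topo$name)
  x <- cbind(
    position = variants$pos,
    cls_ind,
    reg_ind,
    d_hydropathy = aa_hydropathy[variants$alt] - aa_hydropathy[variants$ref],
    d_charge = aa_charge[variants$alt] - aa_charge[variants$ref],
    d_volume = aa_volume[variants$alt] - aa_volume[variants$ref],
    blosum62 = blosum62_score(variants$ref, variants$alt),
    proline_introduced = as.numeric(variants$alt == "P" & variants$ref != "P"),
    glycine_removed = as.numeric(variants$ref == "G" & variants$alt != "G")
  )
  rownames(x) <- variants$label
  x
}

#' Build a structure model from per-residue coordinates
#'
#' @param coords numeric matrix L x 3 of C-alpha coordinates (rows may be
#'   NA when a residue is unresolved).
#' @param plddt per-residue confidence in 0-100 (AlphaFold-style pLDDT).
#' @return object of class `structure_model`.
#' @export
structure_model <- function(coords, plddt = rep(NA_real_, nrow(coords))) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3L, length(plddt) == nrow(coords))
  structure(list(coords = coords, plddt = as.numeric(plddt)),
            class = "structure_model")
}

#' Read a structure model from a PDB file
#'
#' C-alpha coordinates are extracted per residue; for AlphaFold-style
#' files the B-factor column carries the pLDDT confidence and is read as
#' such.
#'
#' @param path path to a PDB file.
#' @param chain optional chain id.
#' @return a [structure_model()].
#' @export
read_structure_pdb <- function(path, chain = NULL) {
  pdb <- bio3d::read.pdb(path)
  sel <- bio3d::atom.select(pdb, elety = "CA", chain = chain)
  at <- pdb$atom[sel$atom, , drop = FALSE]
  at <- at[!duplicated(at$resno), , drop = FALSE]
  L <- max(at$resno)
  coords <- matrix(NA_real_, nrow = L, ncol = 3)
  plddt <- rep(NA_real_, L)
  coords[at$resno, ] <- as.matrix(at[, c("x", "y", "z")])
  plddt[at$resno] <- at$b
  structure_model(coords, plddt)
}

#' Structure-based features for missense variants
#'
#' Per-residue features from a coordinate model: model confidence (pLDDT),
#' the contact number (C-alpha neighbors within `radius` Angstroms,
#' excluding the residue itself), the relative burial (contact number
#' normalized by the maximum observed contact number, in 0-1), and the
#' distance from the residue to the protein's principal (centroid) axis --
#' a generic proxy for proximity to the translocation pore of a
#' transporter. Residues without coordinates yield `NA` features.
#'
#' @param variants validated variant data.frame.
#' @param model a [structure_model()].
#' @param radius contact radius in Angstroms.
#' @return numeric matrix, rows named by variant label.
#' @export
structure_features <- function(variants, model, radius = 10) {
  stopifnot(inherits(model, "structure_model"))
  coords <- model$coords
  ok <- stats::complete.cases(coords)
  d <- as.matrix(stats::dist(coords[ok, , drop = FALSE]))
  contact_ok <- rowSums(d <= radius) - 1L
  contact <- rep(NA_real_, nrow(coords))
  contact[ok] <- contact_ok
  max_contact <- max(contact_ok, 1L)

  ctr <- colMeans(coords[ok, , drop = FALSE])
  cc <- sweep(coords[ok, , drop = FALSE], 2, ctr)
  axis <- svd(cc)$v[, 1]
  proj <- cc %*% axis
  axial <- sqrt(pmax(rowSums(cc^2) - proj^2, 0))
  axis_dist <- rep(NA_real_, nrow(coords))
  axis_dist[ok] <- axial

  p <- variants$pos
  x <- cbind(
    plddt = model$plddt[p],
    contact_number = contact[p],
    rel_burial = contact[p] / max_contact,
    axis_dist = axis_dist[p]
  )
  rownames(x) <- variants$label
  x
}

#' Prediction-based features: join external per-variant score tables
#'
#' Each score table is a data.frame with columns `variant` and `score`
#' (one external predictor per table). Values are joined by variant label;
#' a variant absent from a table gets `NA` (imputed later, at scaling
#' time, with a paired missingness indicator). Duplicate keys within a
#' table are an error.
#'
#' @param variants variant data.frame with a `label` column.
#' @param score_tables named list of data.frames.
#' @return numeric matrix, one column per table, rows named by label.
#' @export
prediction_features <- function(variants, score_tables) {
  stopifnot(is.list(score_tables), length(score_tables) > 0L,
            !is.null(names(score_tables)))
  cols <- lapply(names(score_tables), function(nm) {
    tab <- score_tables[[nm]]
    if (!all(c("variant", "score") %in% names(tab))) {
      stop("score table '", nm, "' needs columns variant, score",
           call. = FALSE)
    }
    if (anyDuplicated(tab$variant)) {
      stop("duplicate variant key(s) in score table '", nm, "'",
           call. = FALSE)
    }
    tab$score[match(variants$label, tab$variant)]
  })
  x <- do.call(cbind, cols)
  colnames(x) <- names(score_tables)
  rownames(x) <- variants$label
  x
}

#' Assemble a raw feature matrix for one feature set
#'
#' @param variants validated variant data.frame.
#' @param seq,topo sequence and topology (needed for the sequence set).
#' @param structure a [structure_model()] (needed for the structure set).
#' @param score_tables named list of score tables (prediction set).
#' @param feature_set one of `"sequence"`, `"structure"`, `"prediction"`,
#'   `"all"`.
#' @param radius contact radius for structure features.
#' @return numeric matrix (raw, unscaled), rows named by variant label.
#' @export
assemble_features <- function(variants, seq = NULL, topo = NULL,
                              structure = NULL, score_tables = NULL,
                              feature_set = c("all", "sequence", "structure",
                                              "prediction"),
                              radius = 10) {
  feature_set <- match.arg(feature_set)
  parts <- list()
  if (feature_set %in% c("sequence", "all")) {
    if (is.null(seq) || is.null(topo)) {
      stop("sequence feature set requires `seq` and `topo`", call. = FALSE)
    }
    parts$sequence <- sequence_features(variants, seq, topo)
  }
  if (feature_set %in% c("structure", "all")) {
    if (is.null(structure)) {
      stop("structure feature set requires `structure`", call. = FALSE)
    }
    parts$structure <- structure_features(variants, structure, radius)
  }
  if (feature_set %in% c("prediction", "all")) {
    if (is.null(score_tables)) {
      stop("prediction feature set requires `score_tables`", call. = FALSE)
    }
    parts$prediction <- prediction_features(variants, score_tables)
  }
  do.call(cbind, unname(parts))
}

#' Fit 0-1 feature scaling (with imputation) on training rows
#'
#' Records, per column: the training mean used to impute missing values,
#' and the (min, max) of the imputed training column for scaling to
#' `[0, 1]`. Columns containing any missing value in training get a
#' companion `<name>_missing` indicator column. Constant columns scale to
#' 0 everywhere (not NaN) and are reported in the `constant` field; an L1
#' penalty zeroes them anyway.
#'
#' @param x raw numeric training matrix.
#' @return object of class `feature_scaling`.
#' @export
fit_feature_scaling <- function(x) {
  x <- as.matrix(x)
  impute_mean <- apply(x, 2, function(col) {
    m <- mean(col, na.rm = TRUE)
    if (!is.finite(m)) 0 else m
  })
  has_missing <- apply(x, 2, anyNA)
  xi <- x
  for (j in which(has_missing)) xi[is.na(xi[, j]), j] <- impute_mean[j]
  mins <- apply(xi, 2, min)
  maxs <- apply(xi, 2, max)
  structure(list(features = colnames(x), min = mins, max = maxs,
                 impute_mean = impute_mean, has_missing = has_missing,
                 constant = colnames(x)[maxs == mins]),
            class = "feature_scaling")
}

#' Apply fitted 0-1 scaling to a raw feature matrix
#'
#' Missing values are imputed with the stored training means (with the
#' companion missingness indicator set to 1); values are scaled with the
#' stored training (min, max) and new rows falling outside the training
#' range are clipped to `[0, 1]`. Training rows therefore reproduce values
#' exactly in `[0, 1]` with column min 0 and max 1 for non-constant
#' columns.
#'
#' @param x raw numeric matrix with the same columns the scaling was
#'   fitted on.
#' @param scaling a [fit_feature_scaling()] result.
#' @return scaled numeric matrix (possibly with extra `_missing` columns).
#' @export
scale_features <- function(x, scaling) {
  if (!inherits(scaling, "feature_scaling")) {
    stop("scaling has not been fitted", call. = FALSE)
  }
  x <- as.matrix(x)
  if (!identical(colnames(x), scaling$features)) {
    stop("feature columns do not match the fitted scaling", call. = FALSE)
  }
  miss_cols <- NULL
  if (any(scaling$has_missing)) {
    miss_cols <- sapply(which(scaling$has_missing),
                        function(j) as.numeric(is.na(x[, j])))
    miss_cols <- matrix(miss_cols, nrow = nrow(x))
    colnames(miss_cols) <-
      paste0(scaling$features[scaling$has_missing], "_missing")
  }
  for (j in seq_len(ncol(x))) {
    x[is.na(x[, j]), j] <- scaling$impute_mean[j]
  }
  rng <- scaling$max - scaling$min
  out <- sweep(x, 2, scaling$min)
  nz <- rng > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, rng[nz], "/")
  out[, !nz] <- 0
  out[out < 0] <- 0
  out[out > 1] <- 1
  if (!is.null(miss_cols)) out <- cbind(out, miss_cols)
  out
}
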