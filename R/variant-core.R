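#' Construct a protein sequence object
#'
#' A minimal container for a single protein chain: an identifier plus the
#' ordered one-letter residues at positions 1..L. Only the 20 canonical
#' amino acids are allowed.
#'
#' @param residues character vector of single letters, or a single string.
#' @param id text identifier.
#' @return an object of class `protein_sequence` with elements `id` and
#'   `residues`.
#' @export
protein_sequence <- function(residues, id = "protein") {
  if (length(residues) == 1L && nchar(residues) > 1L) {
    residues <- strsplit(residues, "")[[1]]
  }
  residues <- toupper(as.character(residues))
  if (length(residues) < 1L) {
    stop("protein sequence must contain at least one residue", call. = FALSE)
  }
  bad <- setdiff(unique(residues), aa_alphabet)
  if (length(bad) > 0L) {
    stop("non-canonical amino-acid code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(id = id, residues = residues), class = "protein_sequence")
}

#' @export
length.protein_sequence <- function(x) length(x$residues)

#' @export
print.protein_sequence <- function(x, ...) {
  cat("protein_sequence", x$id, "(", length(x), "residues )\n")
  invisible(x)
}

#' Read a single protein sequence from a FASTA file
#'
#' @param path path to a FASTA file.
#' @param id optional record id to select when the file holds several
#'   records; with more than one record and no `id`, an error is raised.
#' @return a [protein_sequence()].
#' @export
read_protein_fasta <- function(path, id = NULL) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  if (is.null(id)) {
    if (length(seqs) > 1L) {
      stop("FASTA file has ", length(seqs),
           " records; supply `id` to select one", call. = FALSE)
    }
    rec <- 1L
  } else {
    hit <- which(vapply(names(seqs), function(n) {
      strsplit(n, "\\s+")[[1]][1] == id
    }, logical(1)))
    if (length(hit) != 1L) stop("record '", id, "' not found", call. = FALSE)
    rec <- hit
  }
  protein_sequence(as.character(seqs[[rec]]),
                   id = strsplit(names(seqs)[rec], "\\s+")[[1]][1])
}

#' Parse short-form protein HGVS labels (p.Ref<Pos>Alt)
#'
#' Parses labels like `"p.V216L"` into position, reference and alternate
#' residues. Vectorized; round-trips through [format_hgvs_p()].
#'
#' @param label character vector of HGVS-p short-form labels.
#' @return a data.frame with columns `label`, `pos`, `ref`, `alt`.
#' @export
parse_hgvs_p <- function(label) {
  label <- as.character(label)
  m <- regmatches(label, regexec("^p\\.([A-Za-z])([0-9]+)([A-Za-z])$", label))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) {
    stop("malformed HGVS-p label(s): ", paste(label[bad], collapse = ", "),
         call. = FALSE)
  }
  ref <- toupper(vapply(m, `[`, character(1), 2L))
  pos <- as.integer(vapply(m, `[`, character(1), 3L))
  alt <- toupper(vapply(m, `[`, character(1), 4L))
  noncanon <- !(ref %in% aa_alphabet) | !(alt %in% aa_alphabet)
  if (any(noncanon)) {
    stop("non-canonical amino-acid code in label(s): ",
         paste(label[noncanon], collapse = ", "), call. = FALSE)
  }
  syn <- ref == alt
  if (any(syn)) {
    stop("synonymous variant(s) not allowed (ref == alt): ",
         paste(label[syn], collapse = ", "), call. = FALSE)
  }
  if (any(pos < 1L)) stop("residue position must be >= 1", call. = FALSE)
  data.frame(label = format_hgvs_p(pos, ref, alt), pos = pos,
             ref = ref, alt = alt, stringsAsFactors = FALSE)
}

#' @rdname parse_hgvs_p
#' @param pos,ref,alt components of a missense variant.
#' @export
format_hgvs_p <- function(pos, ref, alt) {
  paste0("p.", ref, pos, alt)
}

#' Validate missense variants against a bound protein sequence
#'
#' Checks that each variant's reference residue matches the sequence at its
#' position. Returns the variants unchanged on success.
#'
#' @param variants data.frame as returned by [parse_hgvs_p()].
#' @param seq a [protein_sequence()].
#' @return `variants`, invisibly unchanged.
#' @export
validate_against_sequence <- function(variants, seq) {
  stopifnot(inherits(seq, "protein_sequence"))
  L <- length(seq)
  oob <- variants$pos < 1L | variants$pos > L
  if (any(oob)) {
    stop("variant position(s) outside 1..", L, ": ",
         paste(variants$label[oob], collapse = ", "), call. = FALSE)
  }
  observed <- seq$residues[variants$pos]
  mism <- observed != variants$ref
  if (any(mism)) {
    i <- which(mism)[1]
    stop("reference mismatch at position ", variants$pos[i],
         ": variant says ", variants$ref[i], ", sequence has ", observed[i],
         " (", sum(mism), " mismatching variant(s) in total)", call. = FALSE)
  }
  variants
}

#' Read and validate a membrane topology region table
#'
#' The table is tab-separated with header columns `name`, `class`, `start`,
#' `end`; regions must be contiguous, non-overlapping 1-based closed
#' intervals covering positions 1..L exactly, with classes drawn from
#' N-term, TM, EL, IL, C-term.
#'
#' @param path path to the topology TSV.
#' @param L optional expected protein length for coverage validation.
#' @return a data.frame of class `topology_map`.
#' @export
read_topology <- function(path, L = NULL) {
  topo <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  topology_map(topo, L = L)
}

#' @rdname read_topology
#' @param regions data.frame with columns name, class, start, end.
#' @export
topology_map <- function(regions, L = NULL) {
  required <- c("name", "class", "start", "end")
  if (!all(required %in% names(regions))) {
    stop("topology table needs columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  regions$start <- as.integer(regions$start)
  regions$end <- as.integer(regions$end)
  classes <- c("N-term", "TM", "EL", "IL", "C-term")
  bad <- setdiff(unique(regions$class), classes)
  if (length(bad) > 0L) {
    stop("unknown region class(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  regions <- regions[order(regions$start), , drop = FALSE]
  if (regions$start[1] != 1L) {
    stop("topology must start at position 1", call. = FALSE)
  }
  if (any(regions$end < regions$start)) {
    stop("region end before start", call. = FALSE)
  }
  if (nrow(regions) > 1L) {
    gaps <- regions$start[-1] != regions$end[-nrow(regions)] + 1L
    if (any(gaps)) {
      stop("topology regions must be contiguous and non-overlapping",
           call. = FALSE)
    }
  }
  if (anyDuplicated(regions$name)) {
    stop("duplicate region name(s)", call. = FALSE)
  }
  if (!is.null(L) && regions$end[nrow(regions)] != L) {
    stop("topology covers 1..", regions$end[nrow(regions)],
         " but sequence length is ", L, call. = FALSE)
  }
  rownames(regions) <- NULL
  class(regions) <- c("topology_map", "data.frame")
  regions
}

#' Map residue positions to topological regions
#'
#' @param pos integer vector of 1-based residue positions.
#' @param topo a `topology_map`.
#' @return data.frame with columns `pos`, `name`, `class`.
#' @export
region_of <- function(pos, topo) {
  stopifnot(inherits(topo, "topology_map"))
  L <- topo$end[nrow(topo)]
  if (any(pos < 1L | pos > L)) {
    stop("position(s) outside 1..", L, call. = FALSE)
  }
  idx <- findInterval(pos, topo$start)
  data.frame(pos = pos, name = topo$name[idx], class = topo$class[idx],
             stringsAsFactors = FALSE)
}

#' Per-region variant characterization density
#'
#' Density of assayed variants per topological region: the number of
#' variants falling in each region divided by the region length in
#' residues. Multiple substitutions at one position count separately
#' (variants, not positions, are counted). Duplicate variant labels are a
#' hard error: a variant set is keyed by label.
#'
#' @param variants data.frame with columns `label` and `pos`.
#' @param topo a `topology_map`.
#' @return list with `regions` (data.frame: name, class, length, n_variants,
#'   density) and `overall` (total variants / protein length).
#' @export
region_density <- function(variants, topo) {
  stopifnot(inherits(topo, "topology_map"))
  if (anyDuplicated(variants$label)) {
    stop("duplicate variant label(s): ",
         paste(unique(variants$label[duplicated(variants$label)]),
               collapse = ", "), call. = FALSE)
  }
  L <- topo$end[nrow(topo)]
  reg <- region_of(variants$pos, topo)
  counts <- table(factor(reg$name, levels = topo$name))
  len <- topo$end - topo$start + 1L
  out <- data.frame(
    name = topo$name, class = topo$class, length = len,
    n_variants = as.integer(counts),
    density = as.integer(counts) / len,
    stringsAsFactors = FALSE
  )
  list(regions = out, overall = nrow(variants) / L)
}
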