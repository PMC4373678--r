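# Readers and validation for the per-protein evidence bundle consumed by
# the ten parameter scorers.  Sequence formats go through Biostrings,
# coordinates through bio3d, Clustal alignments through seqinr.

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @param type `"protein"` or `"dna"`; symbols outside the canonical
#'   alphabet (20 residues, or ACGT) are rejected.
#' @return Named character vector of uppercased sequences, file order kept.
#' @export
read_fasta <- function(path, type = c("protein", "dna")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  # Biostrings silently drops symbols outside its alphabet (warning only);
  # promote that to an error so corrupt records cannot slip through.
  set <- withCallingHandlers(
    tryCatch(
      if (type == "protein") Biostrings::readAAStringSet(path)
      else Biostrings::readDNAStringSet(path),
      error = function(e) stop("cannot parse FASTA ", path, ": ",
                               conditionMessage(e), call. = FALSE)),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w)))
        stop("illegal symbol in FASTA ", path, call. = FALSE)
      invokeRestart("muffleWarning")
    })
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  alphabet <- if (type == "protein") AA_ALPHABET else c("A", "C", "G", "T")
  for (i in seq_along(seqs)) {
    found <- unique(strsplit(seqs[[i]], "")[[1]])
    bad <- setdiff(found, alphabet)
    if (length(bad))
      stop(sprintf("illegal %s symbol(s) %s in record '%s'", type,
                   paste(bad, collapse = ""), names(seqs)[i]), call. = FALSE)
  }
  seqs
}

#' Read atom records from a PDB file
#'
#' Keeps `ATOM` records of the first model only.  Where alternate
#' locations duplicate an atom, the highest-occupancy one is kept
#' (alphabetical altloc id breaking occupancy ties).
#'
#' @param path PDB file.
#' @return data.frame with columns `chain`, `resno`, `resid`, `elety`,
#'   `x`, `y`, `z`.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
                  error = function(e) stop("cannot parse PDB ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path, call. = FALSE)
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  at <- at[order(at$chain, at$resno, at$elety, -at$o, at$alt), , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$elety)), , drop = FALSE]
  out <- at[order(at$chain, at$resno), c("chain", "resno", "resid", "elety", "x", "y", "z")]
  rownames(out) <- NULL
  out
}

#' Read a multiple sequence alignment
#'
#' @param path Aligned FASTA or Clustal file.
#' @param format `"fasta"` or `"clustal"`.
#' @param target Identifier of the target (scored) sequence; must be
#'   present in the alignment.
#' @return An object of class `"msa"`: list with `ids`, `seqs` (aligned,
#'   uppercase, `-` gaps), `width` and `target`.
#' @export
read_msa <- function(path, format = c("fasta", "clustal"), target) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    seqs <- toupper(as.character(set))
    names(seqs) <- sub("\\s.*$", "", names(set))
  } else {
    seqs <- read_clustal_blocks(path)
  }
  if (length(seqs) < 2L) stop("alignment needs at least two sequences", call. = FALSE)
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L)
    stop("ragged alignment: row lengths ", paste(unique(widths), collapse = ", "),
         call. = FALSE)
  if (!target %in% names(seqs))
    stop(sprintf("target id '%s' absent from alignment", target), call. = FALSE)
  structure(list(ids = names(seqs), seqs = seqs, width = widths[[1]],
                 target = target), class = "msa")
}

# Clustal block format: a header line, then blocks of `name  sequence`
# rows; conservation rows (leading whitespace) and blanks are skipped and
# per-name chunks concatenated across blocks.
read_clustal_blocks <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^CLUSTAL", lines[[1]], ignore.case = TRUE))
    stop("not a Clustal alignment: ", path, call. = FALSE)
  body <- lines[-1]
  body <- body[nzchar(trimws(body)) & !grepl("^\\s", body)]
  if (!length(body)) stop("empty Clustal alignment: ", path, call. = FALSE)
  m <- regmatches(body, regexec("^(\\S+)\\s+([A-Za-z.~-]+)\\s*\\d*$", body))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad))
    stop("malformed Clustal row: ", body[which(bad)[1]], call. = FALSE)
  nm <- vapply(m, `[[`, character(1), 2L)
  chunk <- vapply(m, `[[`, character(1), 3L)
  seqs <- vapply(split(chunk, factor(nm, levels = unique(nm))),
                 paste, character(1), collapse = "")
  toupper(chartr("~.", "--", seqs))
}

#' Map target-sequence positions to alignment columns
#'
#' Gap-aware bijection between ungapped positions of the target sequence
#' and its non-gap alignment columns.
#'
#' @param msa An `"msa"` object.
#' @return Integer vector: element `i` is the alignment column holding
#'   target position `i`.
#' @export
msa_position_map <- function(msa) {
  stopifnot(inherits(msa, "msa"))
  chars <- strsplit(msa$seqs[[msa$target]], "")[[1]]
  which(!chars %in% c("-", "."))
}

#' Extract the alignment column for a target position
#'
#' @inheritParams msa_position_map
#' @param position 1-based position in the ungapped target sequence.
#' @return Named character vector: one aligned residue (or `-`) per
#'   sequence at that column.
#' @export
msa_column <- function(msa, position) {
  map <- msa_position_map(msa)
  if (position < 1L || position > length(map))
    stop(sprintf("position %d maps outside the target sequence (length %d)",
                 position, length(map)), call. = FALSE)
  col <- map[[position]]
  vapply(msa$seqs, function(s) substr(s, col, col), character(1))
}

#' Read per-residue secondary-structure / accessibility annotations
#'
#' @param path TSV with header `position ss rsa`; `ss` in {H,E,C}, `rsa`
#'   in \[0,1\].
#' @return data.frame with those columns.
#' @export
read_annotations <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("position", "ss", "rsa") %in% names(df)))
  validate_annotations(df)
  df
}

validate_annotations <- function(df) {
  if (!all(df$ss %in% c("H", "E", "C")))
    stop("ss must be one of H, E, C", call. = FALSE)
  if (any(df$rsa < 0 | df$rsa > 1))
    stop("rsa must lie in [0,1]", call. = FALSE)
  if (any(df$position < 1) || anyDuplicated(df$position))
    stop("annotation positions must be unique and >= 1", call. = FALSE)
  invisible(df)
}

#' Read a codon -> tRNA-abundance table
#'
#' @param path TSV with header `codon aa abundance`.  At most the 61 sense
#'   codons, each once; abundances are non-negative relative numbers
#'   (codon-usage frequencies or tRNA gene-copy counts both work).
#' @return data.frame with those columns.
#' @export
read_codon_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("codon", "aa", "abundance") %in% names(df)))
  df$codon <- toupper(chartr("U", "T", df$codon))
  validate_codon_table(df)
  df
}

validate_codon_table <- function(df) {
  if (anyDuplicated(df$codon))
    stop("duplicated codon in table", call. = FALSE)
  if (nrow(df) > 61L) stop("more than 61 sense codons", call. = FALSE)
  if (any(df$abundance < 0)) stop("abundance must be >= 0", call. = FALSE)
  tr <- vapply(df$codon, translate_codon, character(1))
  bad <- df$codon[tr != df$aa]
  if (length(bad))
    stop("codon/aa mismatch for: ", paste(bad, collapse = ", "), call. = FALSE)
  invisible(df)
}

#' Read the curated functional-site configuration
#'
#' @param path YAML with keys `catalytic_residues`, `glycosylated_asn`,
#'   `ca_ligands`, `dimer_interface` (position lists) and
#'   `proximity_cutoff` (Angstrom).
#' @return A list with those elements (integer vectors / numeric cutoff).
#' @export
read_site_config <- function(path) {
  cfg <- yaml::yaml.load_file(path)
  site_config(catalytic_residues = cfg$catalytic_residues,
              glycosylated_asn = cfg$glycosylated_asn,
              ca_ligands = cfg$ca_ligands,
              dimer_interface = cfg$dimer_interface,
              proximity_cutoff = cfg$proximity_cutoff)
}

#' @rdname read_site_config
#' @param catalytic_residues,glycosylated_asn,ca_ligands,dimer_interface
#'   Integer position vectors (1-based).
#' @param proximity_cutoff Heavy-atom distance cutoff in Angstrom (> 0).
#' @export
site_config <- function(catalytic_residues = integer(), glycosylated_asn = integer(),
                        ca_ligands = integer(), dimer_interface = integer(),
                        proximity_cutoff = 8) {
  out <- list(catalytic_residues = as.integer(catalytic_residues),
              glycosylated_asn = as.integer(glycosylated_asn),
              ca_ligands = as.integer(ca_ligands),
              dimer_interface = as.integer(dimer_interface),
              proximity_cutoff = as.numeric(proximity_cutoff))
  for (k in names(out)[1:4]) if (any(out[[k]] < 1L))
    stop("site positions must be >= 1 (", k, ")", call. = FALSE)
  if (length(out$proximity_cutoff) != 1L || out$proximity_cutoff <= 0)
    stop("proximity_cutoff must be a single positive distance", call. = FALSE)
  out
}

#' Read external per-mutation stability calls
#'
#' @param path TSV with header `mutation value` (raw predictor margin) or
#'   `mutation class` (direct 0/1/2 call).
#' @return data.frame with columns `mutation` and `value` and/or `class`.
#' @export
read_stability_calls <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!"mutation" %in% names(df) || !any(c("value", "class") %in% names(df)))
    stop("stability table needs columns mutation + value and/or class",
         call. = FALSE)
  if ("class" %in% names(df) && !all(is.na(df$class) | df$class %in% 0:2))
    stop("stability class must be 0, 1 or 2", call. = FALSE)
  df
}

#' Assemble an evidence bundle
#'
#' Collects every input a de-novo scoring run consumes.  Use
#' [validate_bundle()] to check cross-field consistency.
#'
#' @param protein_seq Amino-acid string (1-letter codes).
#' @param cds Coding DNA string; must translate to `protein_seq`
#'   (a trailing stop codon is allowed).
#' @param codon_table data.frame as from [read_codon_table()].
#' @param structure data.frame as from [read_structure()], or `NULL`.
#' @param annotations data.frame as from [read_annotations()].
#' @param msa `"msa"` object ([read_msa()]).
#' @param sites List as from [site_config()].
#' @param stability data.frame as from [read_stability_calls()].
#' @return An object of class `"evidence_bundle"`.
#' @export
evidence_bundle <- function(protein_seq, cds, codon_table, structure = NULL,
                            annotations, msa, sites, stability) {
  structure(list(protein_seq = toupper(protein_seq),
                 cds = toupper(chartr("U", "T", cds)),
                 codon_table = codon_table, structure = structure,
                 annotations = annotations, msa = msa, sites = sites,
                 stability = stability),
            class = "evidence_bundle")
}

#' Validate an evidence bundle
#'
#' Checks every bundle invariant and returns the violations as data, not
#' as errors: CDS length and translation against the standard genetic
#' code, annotation positions and ranges, the target row of the MSA
#' (ungapped) against the protein sequence, structure residue numbering,
#' and the codon table.
#'
#' @param bundle An `"evidence_bundle"`.
#' @return Object of class `"bundle_validation"`: list with logical
#'   `pass` and a character vector `violations`.
#' @export
validate_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "evidence_bundle"))
  v <- character()
  n <- nchar(bundle$protein_seq)
  aa_found <- unique(strsplit(bundle$protein_seq, "")[[1]])
  if (length(setdiff(aa_found, AA_ALPHABET)))
    v <- c(v, "protein sequence contains non-canonical symbols")
  nc <- nchar(bundle$cds)
  if (nc != 3L * n && nc != 3L * n + 3L) {
    v <- c(v, sprintf("cds length %d incompatible with protein length %d", nc, n))
  } else {
    tr <- as.character(Biostrings::translate(
      Biostrings::DNAString(substr(bundle$cds, 1L, 3L * n)),
      no.init.codon = TRUE))
    if (tr != bundle$protein_seq) {
      at <- which(strsplit(tr, "")[[1]] != strsplit(bundle$protein_seq, "")[[1]])
      v <- c(v, sprintf("translation mismatch at %s",
                        paste(at, collapse = ", ")))
    }
    if (nc == 3L * n + 3L &&
        !substr(bundle$cds, nc - 2L, nc) %in% c("TAA", "TAG", "TGA"))
      v <- c(v, "trailing codon is not a stop codon")
  }
  ann <- bundle$annotations
  if (!is.null(ann)) {
    if (any(ann$position > n)) v <- c(v, "annotation positions exceed protein length")
    if (!all(ann$ss %in% c("H", "E", "C"))) v <- c(v, "annotation ss outside {H,E,C}")
    if (any(ann$rsa < 0 | ann$rsa > 1)) v <- c(v, "annotation rsa outside [0,1]")
  }
  if (!is.null(bundle$msa)) {
    if (!bundle$msa$target %in% bundle$msa$ids) {
      v <- c(v, "msa target id missing")
    } else {
      ungapped <- gsub("[-.]", "", bundle$msa$seqs[[bundle$msa$target]])
      if (ungapped != bundle$protein_seq)
        v <- c(v, "ungapped msa target differs from protein sequence")
    }
  }
  if (!is.null(bundle$structure)) {
    if (any(bundle$structure$resno < 1L | bundle$structure$resno > n))
      v <- c(v, "structure residue ids outside 1..protein length")
  }
  ct_err <- tryCatch({validate_codon_table(bundle$codon_table); NULL},
                     error = conditionMessage)
  if (!is.null(ct_err)) v <- c(v, paste("codon table:", ct_err))
  structure(list(pass = length(v) == 0L, violations = v),
            class = "bundle_validation")
}

#' @export
print.bundle_validation <- function(x, ...) {
  if (x$pass) cat("evidence bundle: all invariants satisfied\n")
  else cat("evidence bundle FAILED validation:\n",
           paste(" -", x$violations, collapse = "\n"), "\n")
  invisible(x)
}
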