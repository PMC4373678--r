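# Mutation labels and the scored-catalogue table.

CATALOGUE_COLUMNS <- c("mutation", paste0("p", 1:10), "total")

#' Parse a missense mutation label
#'
#' Labels follow the `<Wt><Pos><Mut>` convention with 3-letter amino-acid
#' codes and 1-based full-protein numbering, e.g. `"Arg245His"`.
#'
#' @param label Character scalar, e.g. `"Arg245His"`.
#' @param wt_codon,mut_codon Optional 3-nucleotide codons; when given each
#'   must translate (standard genetic code) to the respective residue.
#' @return An object of class `"sgsh_mutation"`: a list with `label`,
#'   `position`, `wt`, `mut` (1-letter codes) and optional codons.
#' @examples
#' m <- parse_mutation_label("Arg245His")
#' m$position  # 245
#' format_mutation_label(m)
#' @export
parse_mutation_label <- function(label, wt_codon = NULL, mut_codon = NULL) {
  stopifnot(is.character(label), length(label) == 1L)
  m <- regmatches(label, regexec("^([A-Za-z]{3})([0-9]+)([A-Za-z]{3})$", label))[[1]]
  if (length(m) != 4L)
    stop(sprintf("malformed mutation label '%s' (expected e.g. 'Ala30Pro')", label),
         call. = FALSE)
  norm3 <- function(x) paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, 3)))
  wt3 <- norm3(m[2]); mut3 <- norm3(m[4])
  for (code in c(wt3, mut3))
    if (!code %in% names(AA_THREE_TO_ONE))
      stop(sprintf("unknown residue code '%s' in label '%s'", code, label),
           call. = FALSE)
  pos <- as.integer(m[3])
  mutation_record(pos, AA_THREE_TO_ONE[[wt3]], AA_THREE_TO_ONE[[mut3]],
                  wt_codon = wt_codon, mut_codon = mut_codon)
}

#' Construct a mutation record
#'
#' @param position 1-based residue index (full-protein numbering).
#' @param wt,mut Wild-type and mutant residues, 1- or 3-letter codes.
#' @inheritParams parse_mutation_label
#' @return An `"sgsh_mutation"` object; see [parse_mutation_label()].
#' @export
mutation_record <- function(position, wt, mut, wt_codon = NULL, mut_codon = NULL) {
  to1 <- function(x) {
    if (nchar(x) == 3L) {
      x3 <- paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, 3)))
      if (!x3 %in% names(AA_THREE_TO_ONE))
        stop(sprintf("unknown residue code '%s'", x), call. = FALSE)
      AA_THREE_TO_ONE[[x3]]
    } else toupper(x)
  }
  wt1 <- to1(wt); mut1 <- to1(mut)
  check_aa(c(wt1, mut1))
  position <- as.integer(position)
  if (is.na(position) || position < 1L)
    stop("position must be a positive integer", call. = FALSE)
  if (wt1 == mut1)
    stop(sprintf("identity substitution at position %d (%s)", position, wt1),
         call. = FALSE)
  for (cd in list(wt = wt_codon, mut = mut_codon)) if (!is.null(cd))
    if (!grepl("^[ACGTUacgtu]{3}$", cd))
      stop(sprintf("invalid codon '%s'", cd), call. = FALSE)
  if (!is.null(wt_codon) && translate_codon(wt_codon) != wt1)
    stop(sprintf("wild-type codon %s does not encode %s", wt_codon, wt1),
         call. = FALSE)
  if (!is.null(mut_codon) && translate_codon(mut_codon) != mut1)
    stop(sprintf("mutant codon %s does not encode %s", mut_codon, mut1),
         call. = FALSE)
  structure(list(
    label = paste0(AA_ONE_TO_THREE[[wt1]], position, AA_ONE_TO_THREE[[mut1]]),
    position = position, wt = wt1, mut = mut1,
    wt_codon = if (is.null(wt_codon)) NULL else toupper(chartr("U", "T", wt_codon)),
    mut_codon = if (is.null(mut_codon)) NULL else toupper(chartr("U", "T", mut_codon))),
    class = "sgsh_mutation")
}

#' @rdname parse_mutation_label
#' @param x An `"sgsh_mutation"` object.
#' @export
format_mutation_label <- function(x) {
  stopifnot(inherits(x, "sgsh_mutation"))
  x$label
}

#' @export
print.sgsh_mutation <- function(x, ...) {
  cat(sprintf("<mutation> %s (%s%d%s)\n", x$label, x$wt, x$position, x$mut))
  invisible(x)
}

translate_codon <- function(codon) {
  codon <- toupper(chartr("U", "T", codon))
  as.character(Biostrings::translate(Biostrings::DNAString(codon),
                                     no.init.codon = TRUE))
}

new_catalogue <- function(df, provenance = "unspecified") {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(CATALOGUE_COLUMNS, names(df))
  if (length(missing_cols))
    stop("catalogue is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df <- df[, CATALOGUE_COLUMNS]
  if (nrow(df) == 0L) stop("catalogue has no records", call. = FALSE)
  dup <- df$mutation[duplicated(df$mutation)]
  if (length(dup))
    stop("duplicate mutation labels: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  recs <- lapply(df$mutation, parse_mutation_label)
  for (j in c(paste0("p", 1:10), "total")) {
    v <- df[[j]]
    if (any(is.na(v)) || any(v != as.integer(v)))
      stop(sprintf("malformed value in column %s", j), call. = FALSE)
    df[[j]] <- as.integer(v)
  }
  rng <- function(col, lo, hi) {
    bad <- df$mutation[df[[col]] < lo | df[[col]] > hi]
    if (length(bad))
      stop(sprintf("%s out of range [%d,%d] for: %s", col, lo, hi,
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  for (j in paste0("p", setdiff(1:10, 3))) rng(j, 0L, 1L)
  rng("p3", 0L, 2L)
  sums <- rowSums(df[, paste0("p", 1:10)])
  bad <- df$mutation[sums != df$total]
  if (length(bad))
    stop("total does not equal parameter sum for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  df$position <- vapply(recs, `[[`, integer(1), "position")
  df$wt  <- vapply(recs, `[[`, character(1), "wt")
  df$mut <- vapply(recs, `[[`, character(1), "mut")
  structure(df, provenance = provenance,
            class = c("mutation_catalogue", "data.frame"))
}

#' Read a scored mutation catalogue
#'
#' The on-disk dialect is a UTF-8 tab-separated table with header
#' `mutation p1 .. p10 total`.  On load every row is re-validated: labels
#' must parse and be unique, `p3` lies in 0..2, the other parameters in
#' 0..1, and `total` must equal the recomputed parameter sum.
#'
#' @param path Path to a TSV file.
#' @param provenance Free-text provenance attached to the catalogue.
#' @return A `"mutation_catalogue"`: a data.frame with the twelve table
#'   columns plus derived `position`, `wt`, `mut` columns.
#' @seealso [table1_dataset()] for the bundled reference catalogue.
#' @export
read_catalogue <- function(path, provenance = path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (!identical(header, CATALOGUE_COLUMNS))
    stop("unexpected catalogue header: ", paste(header, collapse = " "),
         call. = FALSE)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  new_catalogue(df, provenance = provenance)
}

#' Write a scored mutation catalogue
#'
#' Writes the tab-separated dialect read by [read_catalogue()]; the
#' round-trip `read_catalogue(write_catalogue(x))` reproduces `x` with
#' byte-stable column order.
#'
#' @param catalogue A `"mutation_catalogue"`.
#' @param path Output path.
#' @export
write_catalogue <- function(catalogue, path) {
  stopifnot(inherits(catalogue, "mutation_catalogue"))
  df <- as.data.frame(catalogue)[, CATALOGUE_COLUMNS]
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Pre-select missense records from a raw mutation list
#'
#' Keeps missense records whose labels are not explicitly excluded; all
#' other mutation classes (nonsense, frameshift, splice, other) are
#' dropped and counted by reason.
#'
#' @param raw data.frame with columns `label` and `class`; `class` must be
#'   one of `missense`, `nonsense`, `frameshift`, `splice`, `other`.
#' @param exclusion_labels Character vector of missense labels to drop
#'   (curation exclusions).
#' @return A list with `kept` (character labels), and `dropped`, a named
#'   integer count per drop reason (one per non-missense class present,
#'   plus `"excluded"`).
#' @export
preselect_missense <- function(raw, exclusion_labels = character()) {
  stopifnot(is.data.frame(raw), all(c("label", "class") %in% names(raw)))
  classes <- c("missense", "nonsense", "frameshift", "splice", "other")
  bad <- setdiff(unique(raw$class), classes)
  if (length(bad))
    stop("unknown mutation class tag: ", paste(bad, collapse = ", "),
         call. = FALSE)
  is_mis <- raw$class == "missense"
  excluded <- is_mis & raw$label %in% exclusion_labels
  tab <- table(factor(raw$class[!is_mis], levels = setdiff(classes, "missense")))
  dropped <- c(setNames(as.integer(tab), names(tab)), excluded = sum(excluded))
  list(kept = raw$label[is_mis & !excluded], dropped = dropped)
}

#' Count distinct mutated positions in a catalogue
#'
#' @param catalogue A `"mutation_catalogue"`.
#' @return Integer count of distinct residue positions.
#' @export
unique_positions <- function(catalogue) {
  stopifnot(inherits(catalogue, "mutation_catalogue"))
  length(unique(catalogue$position))
}

#' @export
print.mutation_catalogue <- function(x, ...) {
  cat(sprintf("<mutation catalogue> %d mutations at %d positions (totals %d..%d)\n",
              nrow(x), unique_positions(x), min(x$total), max(x$total)))
  cat("provenance:", attr(x, "provenance"), "\n")
  invisible(x)
}
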