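# Workflow entry points used by the command-line wrapper: de-novo
# scoring of a mutation list against an evidence bundle, the statistical
# report on a scored catalogue, and the cohort genotype-phenotype
# report.  Reports are plain JSON/TSV.

#' Read a run configuration
#'
#' A single YAML file naming input paths and thresholds; unspecified
#' scorer thresholds fall back to [default_scorer_config()].
#'
#' @param path YAML file.
#' @return Named list with a `scorer` sub-list merged over the defaults.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::yaml.load_file(path)
  cfg$scorer <- utils::modifyList(default_scorer_config(),
                                  if (is.null(cfg$scorer)) list() else cfg$scorer)
  cfg
}

load_bundle_from_config <- function(cfg) {
  need <- c("protein_fasta", "cds_fasta", "codon_table", "annotations",
            "msa", "sites", "stability")
  missing_keys <- setdiff(need, names(cfg))
  if (length(missing_keys))
    stop("config missing evidence paths: ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  msa_format <- if (is.null(cfg$msa_format)) "fasta" else cfg$msa_format
  target <- if (is.null(cfg$msa_target)) "target" else cfg$msa_target
  evidence_bundle(
    protein_seq = read_fasta(cfg$protein_fasta, "protein")[[1]],
    cds = read_fasta(cfg$cds_fasta, "dna")[[1]],
    codon_table = read_codon_table(cfg$codon_table),
    structure = if (is.null(cfg$structure)) NULL else read_structure(cfg$structure),
    annotations = read_annotations(cfg$annotations),
    msa = read_msa(cfg$msa, msa_format, target),
    sites = read_site_config(cfg$sites),
    stability = read_stability_calls(cfg$stability))
}

#' Score a mutation list against an evidence bundle
#'
#' Validates the bundle, runs [score_all()] on every mutation, and
#' (optionally) writes the scored catalogue TSV plus a JSON-lines
#' rationale file.
#'
#' @param mutations Character vector of labels, or a data.frame with
#'   columns `label` and optionally `wt_codon` / `mut_codon`.
#' @param bundle An `"evidence_bundle"`.
#' @param config Scorer thresholds ([default_scorer_config()]).
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return A `"mutation_catalogue"` of the scored mutations (invisibly
#'   `NULL` for an empty list, with a warning).
#' @export
run_scoring <- function(mutations, bundle, config = default_scorer_config(),
                        out_dir = NULL) {
  check <- validate_bundle(bundle)
  if (!check$pass)
    stop("evidence bundle failed validation:\n  - ",
         paste(check$violations, collapse = "\n  - "), call. = FALSE)
  if (is.character(mutations))
    mutations <- data.frame(label = mutations, stringsAsFactors = FALSE)
  if (nrow(mutations) == 0L) {
    warning("empty mutation list: nothing to score")
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      writeLines(paste(CATALOGUE_COLUMNS, collapse = "\t"),
                 file.path(out_dir, "scored_catalogue.tsv"))
    }
    return(invisible(NULL))
  }
  getcol <- function(nm) {
    v <- if (nm %in% names(mutations)) as.character(mutations[[nm]])
         else rep(NA_character_, nrow(mutations))
    v[!is.na(v) & !nzchar(v)] <- NA_character_
    v
  }
  wt_cod <- getcol("wt_codon"); mut_cod <- getcol("mut_codon")
  scored <- lapply(seq_len(nrow(mutations)), function(i) {
    rec <- parse_mutation_label(mutations$label[i],
      wt_codon = if (is.na(wt_cod[i])) NULL else wt_cod[i],
      mut_codon = if (is.na(mut_cod[i])) NULL else mut_cod[i])
    score_all(rec, bundle, config)
  })
  df <- data.frame(mutation = vapply(scored, `[[`, character(1), "mutation"))
  for (k in paste0("p", 1:10))
    df[[k]] <- vapply(scored, `[[`, integer(1), k)
  df$total <- vapply(scored, `[[`, numeric(1), "total")
  catalogue <- new_catalogue(df, provenance = "de-novo scoring run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_catalogue(catalogue, file.path(out_dir, "scored_catalogue.tsv"))
    jsonl <- vapply(scored, function(s)
      jsonlite::toJSON(list(mutation = s$mutation, rationale = s$rationale),
                       auto_unbox = TRUE, digits = NA), character(1))
    writeLines(jsonl, file.path(out_dir, "rationales.jsonl"))
  }
  catalogue
}

#' Statistical report on a scored catalogue
#'
#' Distribution summary ([describe_distribution()]), integer histogram,
#' Gaussian histogram fit ([fit_gaussian()]) and the mean +/- 1 SD band
#' partition.  A fit convergence failure is reported in the result while
#' the remaining statistics are still emitted.
#'
#' @param catalogue A `"mutation_catalogue"`.
#' @param bins Integer histogram range `c(lo, hi)`.
#' @param out Optional path for a JSON report.
#' @return List with `summary`, `histogram`, `fit` (or `NULL`),
#'   `fit_error` (or `NULL`), `bands` (named low/moderate/high counts)
#'   and `band_thresholds`.
#' @export
run_stats <- function(catalogue, bins = c(0L, 11L), out = NULL) {
  stopifnot(inherits(catalogue, "mutation_catalogue"))
  totals <- catalogue$total
  summary <- describe_distribution(totals)
  hist <- score_histogram(totals, bins[1], bins[2])
  fit <- NULL; fit_error <- NULL
  fit <- tryCatch(fit_gaussian(hist$count, hist$center),
                  error = function(e) { fit_error <<- conditionMessage(e); NULL })
  bands <- score_band(totals, summary$mean, summary$sd)
  result <- list(
    summary = unclass(summary),
    histogram = hist,
    fit = if (is.null(fit)) NULL else unclass(fit),
    fit_error = fit_error,
    bands = as.list(table(bands)),
    band_thresholds = c(low = summary$mean - summary$sd,
                        high = summary$mean + summary$sd))
  if (!is.null(out))
    jsonlite::write_json(result, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  result
}

#' Cohort genotype-phenotype report
#'
#' Attaches genotype scores under both combination modes, summarises
#' scores per severity class, and correlates score with ordinal severity
#' ([severity_correlation()]) for the sum and the product rule.
#'
#' @param patients Patient data.frame ([read_patients()], [synth_cohort()]).
#' @param catalogue A `"mutation_catalogue"`.
#' @param out_dir Optional output directory (JSON + TSV report).
#' @return List with `groups` (product-mode [group_summary()]),
#'   `spearman` (per mode), and `n_degenerate_excluded`.
#' @export
run_cohort <- function(patients, catalogue, out_dir = NULL) {
  modes <- c("product", "sum")
  scored <- lapply(setNames(modes, modes), function(m)
    attach_scores(patients, catalogue, mode = m))
  result <- list(
    groups = group_summary(scored$product, "severity"),
    spearman = lapply(scored, function(s) unclass(severity_correlation(s))),
    n_degenerate_excluded = sum(scored$product$degenerate))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(result$groups, file.path(out_dir, "group_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(result[c("spearman", "n_degenerate_excluded")],
                         file.path(out_dir, "cohort_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}
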