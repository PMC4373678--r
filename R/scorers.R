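# The ten per-mutation evidence scorers.  Each returns a "scorer_result"
# holding the parameter number, the integer score and a structured
# rationale (the facts the decision used).  Boundary convention: all
# <=/>= comparisons are inclusive toward scoring 1, except the strict
# codon-abundance ratio of parameter 1.

scorer_result <- function(parameter, score, rationale) {
  max_s <- if (parameter == 3L) 2L else 1L
  score <- as.integer(score)
  stopifnot(score >= 0L, score <= max_s)
  structure(list(parameter = as.integer(parameter), score = score,
                 rationale = rationale), class = "scorer_result")
}

#' @export
print.scorer_result <- function(x, ...) {
  cat(sprintf("<parameter %d> score %d\n", x$parameter, x$score))
  invisible(x)
}

#' Default scorer configuration
#'
#' All thresholds used by the ten scorers, overridable per call or via
#' the `config` argument of [score_all()]:
#' \describe{
#'   \item{ratio_threshold}{p1: score 1 when the mutant-codon abundance is
#'     strictly below `ratio_threshold` times the wild-type abundance (0.5).}
#'   \item{delta_threshold}{p2: minimum increase of the normalised
#'     above-threshold profile area that counts as aggregation-promoting (0).}
#'   \item{stability_thresholds}{p3: `c(severe, mild)` cutoffs on a raw
#'     predictor margin (-1.0, -0.5).}
#'   \item{cf_breaker_threshold}{p4: Chou-Fasman propensity below which a
#'     residue counts as an element breaker (0.75).}
#'   \item{proximity_cutoff}{p5/p10 fallback when the site configuration
#'     carries none (8 Angstrom, heavy-atom minimum distance, inclusive).}
#'   \item{sequon_window}{p6: half-width of the window around a
#'     glycosylated asparagine (2 residues).}
#'   \item{rsa_buried_cutoff}{p8: relative accessibility below which a
#'     residue counts as buried (0.20).}
#'   \item{identity_threshold}{p9: conserved-column identity fraction (0.60).}
#' }
#' @return Named list of defaults.
#' @export
default_scorer_config <- function() {
  list(ratio_threshold = 0.5,
       delta_threshold = 0,
       stability_thresholds = c(severe = -1.0, mild = -0.5),
       cf_breaker_threshold = 0.75,
       proximity_cutoff = 8,
       sequon_window = 2L,
       rsa_buried_cutoff = 0.20,
       identity_threshold = 0.60)
}

codon_abundance <- function(codon, codon_table) {
  i <- match(codon, codon_table$codon)
  if (is.na(i)) stop(sprintf("codon %s not in abundance table", codon),
                     call. = FALSE)
  codon_table$abundance[[i]]
}

# The mutant codon: explicit on the record, otherwise the unique
# single-nucleotide neighbour of the wild-type codon encoding the mutant
# residue (ambiguity or absence is an error).
resolve_mut_codon <- function(mutation, wt_codon) {
  if (!is.null(mutation$mut_codon)) return(mutation$mut_codon)
  bases <- c("A", "C", "G", "T")
  cands <- character()
  for (i in 1:3) for (b in setdiff(bases, substr(wt_codon, i, i))) {
    cand <- wt_codon
    substr(cand, i, i) <- b
    if (translate_codon(cand) == mutation$mut) cands <- c(cands, cand)
  }
  cands <- unique(cands)
  if (length(cands) == 1L) return(cands)
  stop(sprintf("mutant codon for %s is %s from %s; supply mut_codon explicitly",
               mutation$label,
               if (length(cands)) paste("ambiguous:", paste(cands, collapse = "/"))
               else "not a single-nucleotide change", wt_codon),
       call. = FALSE)
}

#' Parameter 1: translation-rate effect via codon/tRNA abundance
#'
#' Compares the relative tRNA abundance of the codons encoding the
#' wild-type and mutant residues; a switch to a markedly rarer codon is
#' taken to slow local translation.
#'
#' @param mutation An `"sgsh_mutation"` ([parse_mutation_label()]).  The
#'   wild-type codon comes from `cds`; the mutant codon from the record,
#'   or derived when a unique single-nucleotide change yields the mutant
#'   residue.
#' @param cds Coding DNA string covering the mutated position.
#' @param codon_table data.frame `codon`/`aa`/`abundance`.
#' @param ratio_threshold Score 1 when
#'   `abundance(mut) < ratio_threshold * abundance(wt)` (strict).
#' @return A `"scorer_result"` (score 0/1; rationale holds both codons
#'   and abundances).
#' @export
score_p1_translation <- function(mutation, cds, codon_table,
                                 ratio_threshold = 0.5) {
  pos <- mutation$position
  cds <- toupper(chartr("U", "T", cds))
  if (nchar(cds) < 3L * pos)
    stop("cds does not cover position ", pos, call. = FALSE)
  wt_codon <- substr(cds, 3L * pos - 2L, 3L * pos)
  if (translate_codon(wt_codon) != mutation$wt)
    stop(sprintf("cds codon %s at position %d does not encode wild-type %s",
                 wt_codon, pos, mutation$wt), call. = FALSE)
  if (!is.null(mutation$wt_codon) && mutation$wt_codon != wt_codon)
    stop(sprintf("record wt codon %s disagrees with cds codon %s",
                 mutation$wt_codon, wt_codon), call. = FALSE)
  mut_codon <- resolve_mut_codon(mutation, wt_codon)
  ab_wt <- codon_abundance(wt_codon, codon_table)
  ab_mut <- codon_abundance(mut_codon, codon_table)
  scorer_result(1L, as.integer(ab_mut < ratio_threshold * ab_wt),
                list(wt_codon = wt_codon, mut_codon = mut_codon,
                     wt_abundance = ab_wt, mut_abundance = ab_mut,
                     ratio_threshold = ratio_threshold))
}

#' Parameter 2: aggregation / hydrophobic propensity
#'
#' Profiles wild-type and mutant sequences with [aggrescan_profile()] and
#' scores 1 when the substitution creates a new hot spot overlapping the
#' mutated position, extends or intensifies an existing one there, or
#' increases the normalised above-threshold profile area by more than
#' `delta_threshold`.
#'
#' @inheritParams score_p1_translation
#' @param protein_seq Wild-type protein sequence.
#' @param delta_threshold Strict minimum increase in `na4vss`.
#' @return A `"scorer_result"` (rationale holds both hot-spot sets and
#'   both `na4vss` values).
#' @export
score_p2_aggregation <- function(mutation, protein_seq, delta_threshold = 0) {
  pos <- mutation$position
  if (pos > nchar(protein_seq))
    stop("position ", pos, " outside the protein sequence", call. = FALSE)
  if (substr(protein_seq, pos, pos) != mutation$wt)
    stop(sprintf("sequence has %s at %d, expected %s",
                 substr(protein_seq, pos, pos), pos, mutation$wt), call. = FALSE)
  mut_seq <- protein_seq
  substr(mut_seq, pos, pos) <- mutation$mut
  pw <- aggrescan_profile(protein_seq)
  pm <- aggrescan_profile(mut_seq)
  hs_w <- hot_spot_at(pw, pos)
  hs_m <- hot_spot_at(pm, pos)
  fired <- NULL
  if (nrow(hs_m) && !nrow(hs_w)) {
    fired <- "new hot spot at site"
  } else if (nrow(hs_m) && nrow(hs_w)) {
    len_m <- hs_m$end[1] - hs_m$start[1]
    len_w <- hs_w$end[1] - hs_w$start[1]
    sum_m <- sum(pm$a4v[hs_m$start[1]:hs_m$end[1]])
    sum_w <- sum(pw$a4v[hs_w$start[1]:hs_w$end[1]])
    if (len_m > len_w) fired <- "hot spot extended"
    else if (sum_m > sum_w) fired <- "hot spot intensified"
  }
  if (is.null(fired) && pm$na4vss - pw$na4vss > delta_threshold)
    fired <- "profile area increased"
  scorer_result(2L, as.integer(!is.null(fired)),
                list(clause = fired,
                     wt_hot_spots = pw$hot_spots, mut_hot_spots = pm$hot_spots,
                     wt_na4vss = pw$na4vss, mut_na4vss = pm$na4vss))
}

#' Parameter 3: protein stability (external predictor pass-through)
#'
#' The stability call comes from an external sequence-structure predictor
#' and is not re-derived here; this parameter carries double weight
#' (0-2).  A direct class is passed through; a raw predictor margin `v`
#' is mapped by `v < severe -> 2`, `severe <= v < mild -> 1`, else 0.
#'
#' @inheritParams score_p1_translation
#' @param stability_calls data.frame `mutation` + `class` and/or `value`.
#' @param thresholds Numeric `c(severe, mild)` cutoffs for raw values.
#' @return A `"scorer_result"` (score 0/1/2).
#' @export
score_p3_stability <- function(mutation, stability_calls,
                               thresholds = c(severe = -1.0, mild = -0.5)) {
  i <- match(mutation$label, stability_calls$mutation)
  if (is.na(i))
    stop("no stability call for ", mutation$label, call. = FALSE)
  cls <- if ("class" %in% names(stability_calls)) stability_calls$class[[i]] else NA
  if (!is.na(cls)) {
    if (!cls %in% 0:2) stop("stability class must be 0, 1 or 2", call. = FALSE)
    return(scorer_result(3L, cls, list(source = "class", class = cls)))
  }
  v <- if ("value" %in% names(stability_calls)) stability_calls$value[[i]] else NA
  if (is.na(v))
    stop("stability call for ", mutation$label, " has neither class nor value",
         call. = FALSE)
  score <- if (v < thresholds[[1]]) 2L else if (v < thresholds[[2]]) 1L else 0L
  scorer_result(3L, score, list(source = "value", value = v,
                                thresholds = thresholds))
}

#' Parameter 4: secondary-structure element disruption
#'
#' A residue inside a helix or strand scores 1 when the mutant residue is
#' a recognised breaker of that element: proline or glycine, or a
#' Chou-Fasman propensity for the element below the breaker threshold
#' while the wild-type's is not.  Coil positions score 0.
#'
#' @inheritParams score_p1_translation
#' @param annotations data.frame `position`/`ss`/`rsa`.
#' @param cf_breaker_threshold Propensity below which a residue breaks
#'   the element.
#' @return A `"scorer_result"`.
#' @export
score_p4_secondary_structure <- function(mutation, annotations,
                                         cf_breaker_threshold = 0.75) {
  i <- match(mutation$position, annotations$position)
  if (is.na(i))
    stop("no annotation at position ", mutation$position, call. = FALSE)
  ss <- annotations$ss[[i]]
  if (ss == "C")
    return(scorer_result(4L, 0L, list(element = "coil")))
  p_wt <- CHOU_FASMAN[[ss]][[mutation$wt]]
  p_mut <- CHOU_FASMAN[[ss]][[mutation$mut]]
  breaker <- mutation$mut %in% c("P", "G") ||
    (p_mut < cf_breaker_threshold && p_wt >= cf_breaker_threshold)
  scorer_result(4L, as.integer(breaker),
                list(element = ss, wt_propensity = p_wt,
                     mut_propensity = p_mut,
                     breaker_threshold = cf_breaker_threshold))
}

# Minimum heavy-atom distance between one residue and a set of residues.
min_residue_distance <- function(structure, from_resno, to_resnos) {
  heavy <- structure[!grepl("^H", structure$elety), , drop = FALSE]
  a <- heavy[heavy$resno == from_resno, c("x", "y", "z"), drop = FALSE]
  b <- heavy[heavy$resno %in% to_resnos, c("x", "y", "z"), drop = FALSE]
  if (nrow(a) == 0L)
    stop("residue ", from_resno, " absent from structure", call. = FALSE)
  if (nrow(b) == 0L)
    stop("target residues absent from structure", call. = FALSE)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") -
    2 * as.matrix(a) %*% t(as.matrix(b))
  sqrt(max(min(d2), 0))
}

#' Parameter 5: proximity to the catalytic site
#'
#' Scores 1 when any heavy atom of the mutated residue lies within the
#' proximity cutoff (inclusive) of any heavy atom of a catalytic residue.
#'
#' @inheritParams score_p1_translation
#' @param structure Atom data.frame ([read_structure()]).
#' @param sites Site configuration ([site_config()]); uses
#'   `catalytic_residues` and `proximity_cutoff`.
#' @return A `"scorer_result"` (rationale holds the minimum distance).
#' @export
score_p5_catalytic_proximity <- function(mutation, structure, sites) {
  if (length(sites$catalytic_residues) == 0L)
    stop("no catalytic residues configured", call. = FALSE)
  d <- min_residue_distance(structure, mutation$position,
                            sites$catalytic_residues)
  scorer_result(5L, as.integer(d <= sites$proximity_cutoff),
                list(min_distance = d, cutoff = sites$proximity_cutoff))
}

# Start positions of N-X-[S/T] sequons (X != P) in a sequence.
find_sequons <- function(seq) {
  aa <- strsplit(seq, "")[[1]]
  n <- length(aa)
  if (n < 3L) return(integer())
  i <- seq_len(n - 2L)
  i[aa[i] == "N" & aa[i + 1L] != "P" & aa[i + 2L] %in% c("S", "T")]
}

#' Parameter 6: N-glycosylation
#'
#' Scans N-X-\[S/T\] sequons (X not proline) in the wild-type and mutant
#' sequences; scores 1 when the substitution destroys or creates a
#' sequon, or lies within `window` residues of a configured glycosylated
#' asparagine.
#'
#' @inheritParams score_p2_aggregation
#' @param sites Site configuration; uses `glycosylated_asn`.
#' @param window Half-width around a glycosylated asparagine (inclusive).
#' @return A `"scorer_result"`.
#' @export
score_p6_glycosylation <- function(mutation, protein_seq, sites, window = 2L) {
  pos <- mutation$position
  if (pos > nchar(protein_seq))
    stop("position ", pos, " outside the protein sequence", call. = FALSE)
  mut_seq <- protein_seq
  substr(mut_seq, pos, pos) <- mutation$mut
  sq_wt <- find_sequons(protein_seq)
  sq_mut <- find_sequons(mut_seq)
  destroyed <- setdiff(sq_wt, sq_mut)
  created <- setdiff(sq_mut, sq_wt)
  near <- length(sites$glycosylated_asn) &&
    any(abs(pos - sites$glycosylated_asn) <= window)
  clause <- c(if (length(destroyed)) "sequon destroyed",
              if (length(created)) "sequon created",
              if (near) "near glycosylated Asn")
  scorer_result(6L, as.integer(length(clause) > 0L),
                list(clause = clause, wt_sequons = sq_wt, mut_sequons = sq_mut,
                     window = window))
}

#' Parameter 7: conformational flexibility and disulfide bonding
#'
#' Proline (backbone constraint, cis/trans isomerisation), glycine
#' (flexibility) and cysteine (disulfide bonding) are special; any
#' substitution removing or introducing one of them scores 1.
#'
#' @inheritParams score_p1_translation
#' @return A `"scorer_result"`.
#' @export
score_p7_flexibility <- function(mutation) {
  hit <- intersect(c(mutation$wt, mutation$mut), c("P", "G", "C"))
  scorer_result(7L, as.integer(length(hit) > 0L), list(residues = hit))
}

#' Parameter 8: surface polarity and charge distribution
#'
#' Scores 1 when (a) a buried residue (`rsa < cutoff`) swaps
#' hydrophobicity class (nonpolar vs polar/charged, either direction),
#' (b) an exposed residue replaces a polar/charged residue with a
#' nonpolar one, or (c) the formal charge class (-/0/+ at pH 7; D,E
#' negative, K,R,H positive) changes.
#'
#' @inheritParams score_p4_secondary_structure
#' @param rsa_buried_cutoff Relative accessibility below which a residue
#'   counts as buried.
#' @return A `"scorer_result"` (rationale names the clause(s) fired).
#' @export
score_p8_surface <- function(mutation, annotations, rsa_buried_cutoff = 0.20) {
  i <- match(mutation$position, annotations$position)
  if (is.na(i))
    stop("no annotation at position ", mutation$position, call. = FALSE)
  rsa <- annotations$rsa[[i]]
  buried <- rsa < rsa_buried_cutoff
  np_wt <- aa_is_nonpolar(mutation$wt)
  np_mut <- aa_is_nonpolar(mutation$mut)
  clause <- c(
    if (buried && np_wt != np_mut) "buried hydrophobicity swap",
    if (!buried && !np_wt && np_mut) "exposed polar to nonpolar",
    if (aa_charge(mutation$wt) != aa_charge(mutation$mut)) "charge class change")
  scorer_result(8L, as.integer(length(clause) > 0L),
                list(clause = clause, rsa = rsa, buried = buried,
                     wt_charge = aa_charge(mutation$wt),
                     mut_charge = aa_charge(mutation$mut)))
}

#' Parameter 9: evolutionary conservation
#'
#' Scores 1 when the fraction of non-gap homolog residues identical to
#' the wild-type residue in the target's alignment column reaches the
#' identity threshold (inclusive).
#'
#' @inheritParams score_p1_translation
#' @param msa `"msa"` object including the target sequence.
#' @param identity_threshold Conservation fraction required.
#' @return A `"scorer_result"` (rationale holds the fraction).
#' @export
score_p9_conservation <- function(mutation, msa, identity_threshold = 0.60) {
  col <- msa_column(msa, mutation$position)
  target_res <- col[[msa$target]]
  if (target_res %in% c("-", "."))
    stop("position maps to a gap in the target row", call. = FALSE)
  if (target_res != mutation$wt)
    stop(sprintf("alignment has %s at position %d, expected %s",
                 target_res, mutation$position, mutation$wt), call. = FALSE)
  hom <- col[setdiff(names(col), msa$target)]
  hom <- hom[!hom %in% c("-", ".")]
  if (length(hom) == 0L)
    stop("no non-gap homolog residues at position ", mutation$position,
         call. = FALSE)
  frac <- mean(hom == mutation$wt)
  scorer_result(9L, as.integer(frac >= identity_threshold),
                list(identity_fraction = frac, n_homologs = length(hom),
                     threshold = identity_threshold))
}

#' Parameter 10: physiological requirements (dimer interface, calcium)
#'
#' Scores 1 when the position is a listed calcium ligand or
#' dimer-interface residue, or (when a structure is available) lies
#' within the proximity cutoff of any listed one.
#'
#' @inheritParams score_p5_catalytic_proximity
#' @param structure Atom data.frame or `NULL`.
#' @return A `"scorer_result"`.
#' @export
score_p10_physiology <- function(mutation, structure, sites) {
  listed <- c(sites$ca_ligands, sites$dimer_interface)
  if (length(listed) == 0L)
    stop("both ca_ligands and dimer_interface are empty", call. = FALSE)
  if (mutation$position %in% listed)
    return(scorer_result(10L, 1L, list(clause = "listed site residue")))
  if (!is.null(structure)) {
    present <- unique(structure$resno)
    targets <- intersect(listed, present)
    if (mutation$position %in% present && length(targets)) {
      d <- min_residue_distance(structure, mutation$position, targets)
      return(scorer_result(10L, as.integer(d <= sites$proximity_cutoff),
                           list(clause = "structural proximity",
                                min_distance = d,
                                cutoff = sites$proximity_cutoff)))
    }
  }
  scorer_result(10L, 0L, list(clause = "not listed, no structural contact"))
}

#' Score a mutation on all ten parameters
#'
#' Runs every scorer against an evidence bundle and assembles the score
#' vector; `total` is the sum of the ten parameter scores (0-11).
#'
#' @param mutation An `"sgsh_mutation"`.
#' @param bundle An `"evidence_bundle"`; [validate_bundle()] should pass.
#' @param config Threshold list, see [default_scorer_config()]; partial
#'   lists are merged over the defaults.
#' @return Object of class `"parameter_scores"`: list with integer
#'   elements `p1` .. `p10`, `total`, and a `rationale` list keyed by
#'   parameter.
#' @export
score_all <- function(mutation, bundle, config = default_scorer_config()) {
  stopifnot(inherits(mutation, "sgsh_mutation"),
            inherits(bundle, "evidence_bundle"))
  config <- utils::modifyList(default_scorer_config(), config)
  runs <- list(
    p1 = function() score_p1_translation(mutation, bundle$cds, bundle$codon_table,
                                         config$ratio_threshold),
    p2 = function() score_p2_aggregation(mutation, bundle$protein_seq,
                                         config$delta_threshold),
    p3 = function() score_p3_stability(mutation, bundle$stability,
                                       config$stability_thresholds),
    p4 = function() score_p4_secondary_structure(mutation, bundle$annotations,
                                                 config$cf_breaker_threshold),
    p5 = function() score_p5_catalytic_proximity(mutation, bundle$structure,
                                                 bundle$sites),
    p6 = function() score_p6_glycosylation(mutation, bundle$protein_seq,
                                           bundle$sites, config$sequon_window),
    p7 = function() score_p7_flexibility(mutation),
    p8 = function() score_p8_surface(mutation, bundle$annotations,
                                     config$rsa_buried_cutoff),
    p9 = function() score_p9_conservation(mutation, bundle$msa,
                                          config$identity_threshold),
    p10 = function() score_p10_physiology(mutation, bundle$structure,
                                          bundle$sites))
  results <- vector("list", 10L)
  names(results) <- names(runs)
  for (k in names(runs)) {
    results[[k]] <- tryCatch(runs[[k]](), error = function(e)
      stop(sprintf("parameter %s failed for %s: %s", sub("^p", "", k),
                   mutation$label, conditionMessage(e)), call. = FALSE))
  }
  scores <- vapply(results, `[[`, integer(1), "score")
  out <- c(as.list(scores), list(total = sum(scores)))
  structure(c(out, list(mutation = mutation$label,
                        rationale = lapply(results, `[[`, "rationale"))),
            class = "parameter_scores")
}

#' @export
print.parameter_scores <- function(x, ...) {
  cat(sprintf("<parameter scores> %s: [%s] total %d\n", x$mutation,
              paste(unlist(x[paste0("p", 1:10)]), collapse = " "), x$total))
  invisible(x)
}
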