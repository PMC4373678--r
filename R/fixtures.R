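# Packaged reference data and synthetic test fixtures.
#
# The toy protein is a designed 60-residue synthetic sequence, not SGSH:
# every feature a scorer consumes (helix, strand, sequon, catalytic
# neighbourhood, calcium ligand, dimer interface, buried core, conserved
# and divergent alignment columns) is planted at a known position, and a
# ground-truth table records which parameter each planted mutation
# must fire.

TABLE1_MD5 <- "b2f27e70084006fa413422d2b1dd9d8b"

#' The bundled scored mutation catalogue
#'
#' 86 scored missense mutations (ten parameter scores plus total each);
#' the packaged file is checksummed at load.
#'
#' @return A `"mutation_catalogue"` with 86 rows.
#' @examples
#' cat86 <- table1_dataset()
#' nrow(cat86)            # 86
#' range(cat86$total)     # 0 7
#' @export
table1_dataset <- function() {
  path <- system.file("extdata", "sgsh_table1_scores.tsv",
                      package = "mpsscore", mustWork = TRUE)
  if (!identical(unname(tools::md5sum(path)), TABLE1_MD5))
    stop("packaged catalogue is corrupted (checksum mismatch)", call. = FALSE)
  read_catalogue(path, provenance = "bundled SGSH missense catalogue (86 mutations)")
}

#' Specification of the synthetic toy evidence bundle
#'
#' @param seed Seed for the randomised homolog columns of the toy MSA.
#' @return A list of design constants consumed by [make_toy_bundle()].
#' @export
toy_bundle_spec <- function(seed = 1L) {
  list(seed = as.integer(seed), length = 60L,
       helix = 10:20, strand = 30:38, buried = 12:18,
       sequon_start = 45L, catalytic = 25L, ca_ligand = 52L,
       dimer_interface = c(55L, 26L), proximity_cutoff = 8,
       rsa_exposed = 0.55, rsa_buried = 0.05,
       n_homologs = 5L, hom_sub_rate = 0.10)
}

toy_protein_sequence <- function(spec) {
  aa <- rep(c("A", "D", "K", "E"), length.out = spec$length)
  aa[5] <- "L"
  aa[10:20] <- c("M", "A", "A", "L", "E", "A", "K", "L", "A", "E", "L")
  aa[23] <- "A"; aa[24] <- "T"          # D22N can create an N-A-T sequon
  aa[25] <- "D"                          # catalytic residue
  aa[26] <- "C"                          # near-active-site / interface
  aa[28] <- "P"
  aa[30:38] <- c("V", rep("T", 8))       # strand; T34W plants a hot spot
  aa[45:47] <- c("N", "A", "S")          # glycosylation sequon
  paste(aa, collapse = "")
}

# Most-abundant codon per residue, from the packaged usage table.
preferred_codons <- function(codon_table) {
  split_tab <- split(codon_table, codon_table$aa)
  vapply(split_tab, function(d) d$codon[which.max(d$abundance)], character(1))
}

toy_msa <- function(spec, protein_seq) {
  aa <- strsplit(protein_seq, "")[[1]]
  n <- spec$length
  fixed_cols <- c(5L, 20L, 21L, 26L, 33L, 34L, 45L, 46L, 47L)
  subs_pool <- c("A", "S", "T", "K", "E", "Q", "D")
  homs <- list()
  for (h in seq_len(spec$n_homologs)) {
    hom <- aa
    hit <- runif(n) < spec$hom_sub_rate & !seq_len(n) %in% fixed_cols
    hom[hit] <- vapply(aa[hit], function(r)
      sample(setdiff(subs_pool, r), 1L), character(1))
    homs[[paste0("homolog", h)]] <- hom
  }
  # column 33: fully divergent; column 21: 1/5 identical; column 26: 2/5
  for (h in 1:5) homs[[h]][33] <- "A"
  for (h in 2:5) homs[[h]][21] <- "S"
  for (h in 3:5) homs[[h]][26] <- "S"
  homs[[5]][1:3] <- "-"
  seqs <- c(target = protein_seq,
            vapply(homs, paste, character(1), collapse = ""))
  structure(list(ids = names(seqs), seqs = seqs, width = n,
                 target = "target"), class = "msa")
}

toy_structure <- function(spec, protein_seq) {
  aa <- strsplit(protein_seq, "")[[1]]
  data.frame(chain = "A", resno = seq_len(spec$length),
             resid = unname(AA_ONE_TO_THREE[aa]),
             elety = "CA",
             x = 3.8 * (seq_len(spec$length) - 1), y = 0, z = 0,
             stringsAsFactors = FALSE)
}

toy_truth <- function() {
  truth <- rbind(
    data.frame(label = "Leu5Val",   parameter = 1L,  expected = 1L, mut_codon = "GTA"),
    data.frame(label = "Thr34Trp",  parameter = 2L,  expected = 1L, mut_codon = NA),
    data.frame(label = "Glu14Lys",  parameter = 3L,  expected = 2L, mut_codon = NA),
    data.frame(label = "Leu17Met",  parameter = 3L,  expected = 2L, mut_codon = NA),
    data.frame(label = "Ala15Pro",  parameter = 4L,  expected = 1L, mut_codon = NA),
    data.frame(label = "Cys26Ser",  parameter = 5L,  expected = 1L, mut_codon = "AGC"),
    data.frame(label = "Glu40Gln",  parameter = 5L,  expected = 0L, mut_codon = NA),
    data.frame(label = "Ser47Ala",  parameter = 6L,  expected = 1L, mut_codon = NA),
    data.frame(label = "Asp22Asn",  parameter = 6L,  expected = 1L, mut_codon = NA),
    data.frame(label = "Glu44Lys",  parameter = 6L,  expected = 1L, mut_codon = NA),
    data.frame(label = "Pro28Ser",  parameter = 7L,  expected = 1L, mut_codon = NA),
    data.frame(label = "Cys26Ser",  parameter = 7L,  expected = 1L, mut_codon = "AGC"),
    data.frame(label = "Leu13Arg",  parameter = 8L,  expected = 1L, mut_codon = NA),
    data.frame(label = "Leu20Phe",  parameter = 9L,  expected = 1L, mut_codon = NA),
    data.frame(label = "Thr33Ala",  parameter = 9L,  expected = 0L, mut_codon = NA),
    data.frame(label = "Glu52Gln",  parameter = 10L, expected = 1L, mut_codon = NA),
    data.frame(label = "Lys55Glu",  parameter = 10L, expected = 1L, mut_codon = NA),
    data.frame(label = "Ala53Ser",  parameter = 10L, expected = 1L, mut_codon = NA),
    data.frame(label = "Cys26Ser",  parameter = 10L, expected = 1L, mut_codon = "AGC"))
  truth$mut_codon <- as.character(truth$mut_codon)
  truth
}

toy_stability <- function(truth) {
  labels <- unique(c(truth$label, "Ala21Ser"))
  st <- data.frame(mutation = labels, class = 0L, value = NA_real_,
                   stringsAsFactors = FALSE)
  st$class[st$mutation == "Glu14Lys"] <- 2L
  st$class[st$mutation == "Leu17Met"] <- NA_integer_
  st$value[st$mutation == "Leu17Met"] <- -1.5
  st
}

#' Build the synthetic toy evidence bundle
#'
#' Deterministic for a given spec; the returned object carries the
#' planted ground truth (`$truth`): for each planted mutation, the
#' parameter it probes and the score that parameter must return.
#'
#' @param spec Design constants, see [toy_bundle_spec()].
#' @return List with `bundle` (an `"evidence_bundle"` that passes
#'   [validate_bundle()]) and `truth` (data.frame `label`, `parameter`,
#'   `expected`, `mut_codon`).
#' @export
make_toy_bundle <- function(spec = toy_bundle_spec()) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  protein <- toy_protein_sequence(spec)
  aa <- strsplit(protein, "")[[1]]
  codon_table <- read_codon_table(system.file("extdata", "human_codon_usage.tsv",
                                              package = "mpsscore", mustWork = TRUE))
  pref <- preferred_codons(codon_table)
  cds <- paste0(paste(pref[aa], collapse = ""), "TAA")
  annotations <- data.frame(position = seq_len(spec$length),
                            ss = "C", rsa = spec$rsa_exposed)
  annotations$ss[spec$helix] <- "H"
  annotations$ss[spec$strand] <- "E"
  annotations$rsa[spec$buried] <- spec$rsa_buried
  sites <- site_config(catalytic_residues = spec$catalytic,
                       glycosylated_asn = spec$sequon_start,
                       ca_ligands = spec$ca_ligand,
                       dimer_interface = spec$dimer_interface,
                       proximity_cutoff = spec$proximity_cutoff)
  truth <- toy_truth()
  bundle <- evidence_bundle(protein_seq = protein, cds = cds,
                            codon_table = codon_table,
                            structure = toy_structure(spec, protein),
                            annotations = annotations,
                            msa = toy_msa(spec, protein),
                            sites = sites,
                            stability = toy_stability(truth))
  list(bundle = bundle, truth = truth)
}

#' Write the toy bundle to files
#'
#' Serialises every bundle component in its on-disk dialect (FASTA, PDB,
#' TSV, YAML) plus the ground-truth table; byte-identical output for
#' identical specs.
#'
#' @inheritParams make_toy_bundle
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_toy_bundle <- function(spec = toy_bundle_spec(), dir) {
  tb <- make_toy_bundle(spec)
  bundle <- tb$bundle
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(protein = "protein.fasta", cds = "cds.fasta",
             codon_table = "codon_usage.tsv", structure = "structure.pdb",
             annotations = "annotations.tsv", msa = "msa.fasta",
             sites = "sites.yaml", stability = "stability.tsv",
             truth = "truth.tsv")
  paths <- vapply(paths, function(p) file.path(dir, p), character(1))
  writeLines(c(">toy_protein synthetic", bundle$protein_seq), paths["protein"])
  writeLines(c(">toy_cds synthetic", bundle$cds), paths["cds"])
  write.table(bundle$codon_table, paths["codon_table"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(format_pdb_atoms(bundle$structure), paths["structure"])
  write.table(bundle$annotations, paths["annotations"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(unlist(lapply(seq_along(bundle$msa$seqs), function(i)
    c(paste0(">", bundle$msa$ids[i]), bundle$msa$seqs[[i]]))), paths["msa"])
  writeLines(yaml::as.yaml(bundle$sites), paths["sites"])
  write.table(bundle$stability, paths["stability"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(tb$truth, paths["truth"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(paths)
}

# Fixed-width PDB ATOM records (CA-trace toys).
format_pdb_atoms <- function(atoms) {
  lines <- vapply(seq_len(nrow(atoms)), function(i)
    sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
            i, paste0(" ", atoms$elety[i]), atoms$resid[i], atoms$chain[i],
            atoms$resno[i], atoms$x[i], atoms$y[i], atoms$z[i], 1, 0),
    character(1))
  c(lines, "END")
}
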