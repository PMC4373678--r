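# Independent oracles and small fixture builders used across the suite.
# Oracles are deliberately written as direct enumerations / closed forms,
# not via the package's own code paths.

# All maximal runs of >= 5 residues with profile > hst and no proline,
# by exhaustive interval enumeration.
brute_hot_spots <- function(a4v, aa, hst) {
  n <- length(a4v)
  ok <- a4v > hst & aa != "P"
  spans <- list()
  for (i in seq_len(n)) for (j in i:n)
    if (j - i + 1L >= 5L && all(ok[i:j]))
      spans[[length(spans) + 1L]] <- c(i, j)
  if (!length(spans)) return(data.frame(start = integer(), end = integer()))
  m <- unique(do.call(rbind, spans))
  keep <- vapply(seq_len(nrow(m)), function(k)
    !any(m[, 1] <= m[k, 1] & m[, 2] >= m[k, 2] &
           (m[, 1] != m[k, 1] | m[, 2] != m[k, 2])), logical(1))
  m <- m[keep, , drop = FALSE]
  m <- m[order(m[, 1]), , drop = FALSE]
  data.frame(start = as.integer(m[, 1]), end = as.integer(m[, 2]))
}

# Mean ranks by counting, then the product-moment formula on ranks.
brute_rank <- function(v) {
  vapply(seq_along(v), function(i)
    sum(v < v[i]) + (sum(v == v[i]) + 1) / 2, numeric(1))
}

brute_spearman <- function(x, y) {
  rx <- brute_rank(x); ry <- brute_rank(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

random_protein <- function(n) {
  paste(sample(mpsscore:::AA_ALPHABET, n, replace = TRUE), collapse = "")
}

# Minimal catalogue data.frame around given totals (p3 absorbs up to 2,
# the remaining weight spills into p1, p2, ...).
toy_catalogue <- function(labels, totals) {
  stopifnot(length(labels) == length(totals), all(totals <= 11))
  rows <- lapply(totals, function(tt) {
    p <- integer(10)
    p[3] <- min(tt, 2L)
    rest <- tt - p[3]
    if (rest > 0) p[setdiff(1:10, 3)[seq_len(rest)]] <- 1L
    p
  })
  df <- data.frame(mutation = labels)
  m <- do.call(rbind, rows)
  for (k in 1:10) df[[paste0("p", k)]] <- m[, k]
  df$total <- totals
  df
}

write_toy_catalogue <- function(labels, totals, path = tempfile(fileext = ".tsv")) {
  write.table(toy_catalogue(labels, totals), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  path
}

# Patient table builder.
patients_df <- function(allele1, allele2, severity = NA_character_,
                        onset = NA_character_) {
  data.frame(patient_id = sprintf("P%03d", seq_along(allele1)),
             allele1 = allele1, allele2 = allele2,
             zygosity = ifelse(allele1 == allele2, "homozygous", "compound_het"),
             onset_class = onset, severity = severity,
             stringsAsFactors = FALSE)
}
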