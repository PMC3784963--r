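# Independent oracles and small fixture builders shared across tests.

AA20 <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

randomAASeq <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

# Brute-force tryptic digest by substring enumeration: a peptide is any
# substring whose left edge follows a K/R (or is the sequence start), whose
# right edge is a K/R (or the sequence end), with at most k internal K/R.
# Independent of the boundary-walking implementation in the package.
bruteDigest <- function(s, k) {
  res <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(res)
  if (n == 0L)
    return(data.frame(peptide = character(), start = integer(),
                      end = integer(), missed_cleavages = integer()))
  isKR <- res %in% c("K", "R")
  S <- cumsum(isKR)
  okStart <- which(c(TRUE, isKR[-n]))
  okEnd <- which(isKR | seq_len(n) == n)
  grid <- expand.grid(start = okStart, end = okEnd)
  grid <- grid[grid$start <= grid$end, ]
  # internal sites: K/R at positions start..end-1; S0[x] = S[x-1]
  S0 <- c(0L, S)
  grid$missed_cleavages <- S0[grid$end] - S0[grid$start]
  grid <- grid[grid$missed_cleavages <= k, ]
  grid$peptide <- substring(s, grid$start, grid$end)
  grid <- grid[order(grid$start, grid$end),
               c("peptide", "start", "end", "missed_cleavages")]
  rownames(grid) <- NULL
  grid
}

# Brute-force observable-peptide count from the substring oracle.
bruteCountObservable <- function(s, window) {
  pep <- unique(bruteDigest(s, window@maxMissedCleavages)$peptide)
  pep <- pep[nchar(pep) >= window@minLength]
  if (!length(pep)) return(0L)
  ok <- rep(FALSE, length(pep))
  for (z in window@charges) {
    mz <- peptideMz(pep, z)
    ok <- ok | (mz >= window@mzMin & mz <= window@mzMax)
  }
  sum(ok)
}

# Small abundance table builder: one row per accession x replicate.
makeAbundance <- function(accession, category, empai, replicate) {
  data.frame(accession = accession,
             locus_tag = paste0("LT", accession),
             category = category, replicate = replicate,
             empai = empai, stringsAsFactors = FALSE)
}

writeTempFasta <- function(headers, seqs) {
  f <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", headers), seqs)), f)
  f
}
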