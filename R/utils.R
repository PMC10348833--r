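# Internal helpers shared across modules.

# Signatures are stored as integer vectors; positive entries are subexon
# indices, a negative entry -k marks the intronic gap between subexons k and
# k+1 (used only by intron-retention fragments). The string key is the
# comma-joined form used in tables and fragment names.
sigKey <- function(sig) paste(sig, collapse = ",")

sigParse <- function(key) {
  if (is.na(key) || !nzchar(key)) return(integer(0))
  as.integer(strsplit(key, ",", fixed = TRUE)[[1L]])
}

# Element-wise sortable key for signature strings ("2,10" sorts after
# "2,4"); offset keeps intron pseudo-entries (negative) sortable.
sigSortKey <- function(keys) {
  vapply(keys, function(k) {
    v <- suppressWarnings(sigParse(k))
    if (anyNA(v)) return(k)   # e.g. paired-end "sig1|sig2" keys
    paste(sprintf("%07d", v + 1000000L), collapse = ",")
  }, character(1), USE.NAMES = FALSE)
}

# Deterministic order for a character vector of signature keys: by first
# index, then element-wise.
sigOrder <- function(keys) order(sigSortKey(keys))

# Is `x` a contiguous subsequence of `y`? Both strictly increasing integer
# vectors.
isContiguousSub <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx == 0L || nx > ny) return(FALSE)
  hits <- which(y == x[1L])
  for (h in hits) {
    if (h + nx - 1L <= ny && all(y[h:(h + nx - 1L)] == x)) return(TRUE)
  }
  FALSE
}

randomDNA <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Run code with a local RNG state seeded from `seed`.
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Number of positions at which two equal-length strings agree.
matchingBases <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  if (length(ra) != length(rb)) return(0L)
  sum(ra == rb)
}

chromSeq <- function(genome, chrom) {
  if (!chrom %in% names(genome))
    stop("no sequence available for chromosome '", chrom, "'")
  genome[[chrom]]
}
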