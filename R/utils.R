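# Internal helpers: deterministic seed streams, k-mer encoding, small checks.

# Derive a reproducible 31-bit child seed for an independent RNG stream.
# Multiplier kept below 2^22 so seed * mult stays exactly representable in a
# double; results are identical across platforms.
child_seed <- function(seed, stream) {
  s <- as.numeric(seed) %% 2147483647
  as.integer((s * 4194301 + as.numeric(stream) * 7919) %% 2147483647)
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

DNA_BASES <- c("A", "C", "G", "T")

# Character genome -> integer codes 0..3 (A,C,G,T), NA for anything else.
base_codes <- function(seq_chr) {
  v <- utf8ToInt(seq_chr)
  out <- rep(NA_integer_, length(v))
  out[v == 65L | v == 97L] <- 0L
  out[v == 67L | v == 99L] <- 1L
  out[v == 71L | v == 103L] <- 2L
  out[v == 84L | v == 116L] <- 3L
  out
}

# Integer id of the k-mer starting at every position 1..(L-k+1);
# id = base-4 number, first base most significant. NA where any base is N.
kmer_start_ids <- function(codes, k) {
  L <- length(codes)
  if (L < k) return(integer(0))
  n <- L - k + 1L
  id <- codes[seq_len(n)]
  if (k > 1) for (j in seq_len(k - 1L)) id <- id * 4L + codes[seq_len(n) + j]
  id
}

# All k-mer strings in id order (AA.., AC.., ...).
kmer_strings <- function(k) {
  if (k == 0) return("")
  g <- expand.grid(rep(list(DNA_BASES), k), stringsAsFactors = FALSE)[, k:1, drop = FALSE]
  do.call(paste0, g)
}

# Map k-mer id -> id of its reverse complement.
revcomp_ids <- function(k) {
  nk <- 4L^k
  ids <- 0:(nk - 1L)
  rc <- integer(nk)
  rem <- ids
  for (j in seq_len(k)) {       # peel digits least-significant first
    digit <- rem %% 4L
    rem <- rem %/% 4L
    rc <- rc * 4L + (3L - digit)
  }
  rc
}

# Offsets of the k-mer attributed to a cut at 1-based position j:
# plus strand window starts at j - floor(k/2) (for k = 2 the dinucleotide
# whose second base is the cut base); minus strand uses the mirror-image
# window, reverse complemented.
kmer_plus_offset <- function(k) -(k %/% 2L)
kmer_minus_offset <- function(k) -(k - 1L - k %/% 2L)

stopifnot_scalar <- function(x, name) {
  if (length(x) != 1 || is.na(x))
    stop(sprintf("'%s' must be a non-missing scalar", name), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Sum of x over [from, to] via cumulative sums (cx = c(0, cumsum(x))).
csum <- function(cx, from, to) cx[to + 1L] - cx[from]
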