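#' @importFrom methods as
#' @importFrom stats rbinom rlnorm rmultinom runif sd setNames wilcox.test
#'   cor t.test
#' @importFrom utils adist head modifyList
NULL

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC ambiguity codes; inosine ("I") in primers is matched as N.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"), I = c("A", "C", "G", "T")
)

#' Reverse complement of nucleotide sequences
#'
#' @param x character vector of DNA sequences (A/C/G/T plus IUPAC codes).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  # Biostrings pays off on large vectors; small calls stay in base R
  if (length(x) >= 1000)
    return(as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(x))))
  comp <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                 "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Does an IUPAC code match a base?
#'
#' Degenerate positions (for example W, Y, R, N, and inosine I treated as N)
#' match every base they encode.
#'
#' @param code single IUPAC character (primer side).
#' @param base single A/C/G/T character (read side).
#' @return logical.
#' @export
iupac_matches <- function(code, base) {
  set <- IUPAC_SETS[[toupper(code)]]
  if (is.null(set)) stop("unknown IUPAC code: ", code)
  toupper(base) %in% set
}

# Run code with a private RNG state seeded by `seed`; the caller's
# .Random.seed is restored on exit.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Character matrix (n x L) from equal-length sequences.
seq_char_matrix <- function(seqs) {
  stopifnot(length(unique(nchar(seqs))) <= 1)
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = length(seqs), byrow = TRUE)
}

# Byte matrix (n x L) from equal-length sequences; one charToRaw call.
seq_raw_matrix <- function(seqs) {
  L <- unique(nchar(seqs))
  stopifnot(length(L) == 1)
  matrix(charToRaw(paste(seqs, collapse = "")), nrow = length(seqs),
         ncol = L, byrow = TRUE)
}

# Pairwise mismatch counts between equal-length pure-ACGT sequence sets,
# via per-base indicator matrix products (O(n * m * L) in BLAS).
mismatch_count_matrix <- function(a, b = a) {
  la <- unique(nchar(a)); lb <- unique(nchar(b))
  stopifnot(length(la) == 1, length(lb) == 1, la == lb)
  ma <- seq_raw_matrix(a)
  mb <- if (identical(a, b)) ma else seq_raw_matrix(b)
  same <- identical(a, b)
  matches <- matrix(0, nrow(ma), nrow(mb))
  for (base in DNA_BASES) {
    code <- as.raw(utf8ToInt(base))
    ia <- matrix(as.numeric(ma == code), nrow(ma))
    ib <- if (same) ia else matrix(as.numeric(mb == code), nrow(mb))
    matches <- matches + tcrossprod(ia, ib)
  }
  out <- la - matches
  storage.mode(out) <- "integer"
  out
}

is_pure_acgt <- function(seqs) {
  !grepl("[^ACGT]", seqs)
}

# round() uses banker's rounding; reported percentages use half-away-from-zero.
round_half_away <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}
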