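#' @keywords internal
"_PACKAGE"

# Row order of the matrices: alphabetical by three-letter amino-acid code,
# the order the published tables are printed in.
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

POSITIONS <- paste0("p", 1:9)

# Residue codes that can appear in real protein records but are undefined in
# a 20-residue matrix: windows containing any of these are never scored.
NONSTANDARD <- c("B", "J", "O", "U", "X", "Z", "*")

#' Round half-up to a fixed number of decimals
#'
#' Rounds half away from zero, matching the convention of the published
#' matrices and score tables (e.g. 0.0005 -> 0.001, -0.0005 -> -0.001),
#' unlike [round()] which rounds half to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 3, the table precision).
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(c(0.3245, -0.3245))
round_half_up <- function(x, digits = 3) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Evaluate `expr` under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Uppercase + strip whitespace; shared by all sequence readers.
clean_seq <- function(x) toupper(gsub("\\s+", "", x))

# Check sequences against an alphabet; returns indices of offenders.
invalid_residues <- function(seqs, alphabet = c(AA20, NONSTANDARD)) {
  pat <- paste0("^[", paste(gsub("\\*", "\\\\*", alphabet), collapse = ""), "]*$")
  which(!grepl(pat, seqs))
}

# Stop unless every element is a valid nonamer over the 20-letter alphabet.
assert_nonamers <- function(x, what = "nonamer") {
  if (length(x) == 0L) stop("empty ", what, " set", call. = FALSE)
  x <- clean_seq(x)
  bad <- which(nchar(x) != 9L | !grepl(paste0("^[", paste(AA20, collapse = ""), "]{9}$"), x))
  if (length(bad))
    stop("invalid ", what, " at index ", bad[1], ": '", x[bad[1]],
         "' (must be 9 residues over the 20-letter alphabet)", call. = FALSE)
  x
}
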