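# The 15-character IUPAC alphabet over {A,C,G,T} and its inclusion lattice.
#
# Characters are handled as bitmasks (A=1, C=2, G=4, T=8); the degeneracy
# level of a character is the size of its base set, and the canonical
# iteration order is levels ascending, lexicographic within a level:
# A,C,G,T,M,R,W,S,Y,K,V,H,D,B,N.

.BASES <- c("A", "C", "G", "T")

.IUPAC_SYMBOL_BY_MASK <- c(
  "A", "C", "M", "G", "R", "S", "V", "T", "W", "Y", "H", "K", "D", "B", "N"
)

.IUPAC_CANONICAL <- c(
  "A", "C", "G", "T", "M", "R", "W", "S", "Y", "K", "V", "H", "D", "B", "N"
)

.mask_of <- function(symbol) {
  m <- match(symbol, .IUPAC_SYMBOL_BY_MASK)
  if (anyNA(m)) {
    stop("invalid IUPAC character(s): ",
         paste(unique(symbol[is.na(m)]), collapse = ", "), call. = FALSE)
  }
  m
}

.level_of_mask <- function(mask) {
  vapply(mask, function(m) sum(bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L), integer(1))
}

.letters_of_mask <- function(mask) {
  .BASES[bitwAnd(mask, c(1L, 2L, 4L, 8L)) > 0L]
}

#' The IUPAC alphabet
#'
#' Returns the 15-character IUPAC alphabet over the DNA bases, one row per
#' character, in the canonical order (degeneracy levels ascending,
#' lexicographic within a level). Each character stands for a non-empty
#' subset of \{A, C, G, T\}; its degeneracy level is the subset size.
#'
#' @return A data frame with columns `symbol`, `letters` (comma-separated
#'   base set) and `level`.
#' @examples
#' iupac_alphabet()
#' @export
iupac_alphabet <- function() {
  mask <- .mask_of(.IUPAC_CANONICAL)
  data.frame(
    symbol = .IUPAC_CANONICAL,
    letters = vapply(mask, function(m) paste(.letters_of_mask(m), collapse = ","),
                     character(1)),
    level = .level_of_mask(mask),
    stringsAsFactors = FALSE
  )
}

#' IUPAC character for a set of bases
#'
#' Maps a non-empty subset of \{A, C, G, T\} to the unique IUPAC character
#' denoting exactly that base set (e.g. \{G, T\} to `K`).
#'
#' @param letters Character vector of distinct DNA bases (a subset of
#'   `c("A","C","G","T")`; lowercase accepted).
#' @return A single IUPAC symbol.
#' @examples
#' character_from_letters(c("G", "T"))  # "K"
#' @export
character_from_letters <- function(letters) {
  letters <- toupper(as.character(letters))
  if (length(letters) == 0) {
    stop("letter set must be non-empty", call. = FALSE)
  }
  idx <- match(letters, .BASES)
  if (anyNA(idx)) {
    stop("letters outside the DNA alphabet: ",
         paste(unique(letters[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  mask <- sum(bitwShiftL(1L, unique(idx) - 1L))
  .IUPAC_SYMBOL_BY_MASK[mask]
}

#' Base set of an IUPAC character
#'
#' @param symbol A single IUPAC symbol.
#' @return Character vector of the DNA bases the symbol stands for.
#' @examples
#' iupac_letters("H")  # A C T
#' @export
iupac_letters <- function(symbol) {
  symbol <- toupper(symbol)
  stopifnot(length(symbol) == 1)
  .letters_of_mask(.mask_of(symbol))
}

#' Degeneracy level of IUPAC characters
#'
#' @param symbol Character vector of IUPAC symbols.
#' @return Integer vector of degeneracy levels (1 for plain bases, 4 for N).
#' @examples
#' iupac_level(c("A", "R", "B", "N"))
#' @export
iupac_level <- function(symbol) {
  .level_of_mask(.mask_of(toupper(symbol)))
}

#' Direct generalizations of an IUPAC character
#'
#' Returns the characters exactly one level above `symbol` in the character
#' inclusion lattice, i.e. whose base set adds one base to that of
#' `symbol`. These are the Hasse-diagram edges of the character lattice;
#' `N` is the top element and has no parents.
#'
#' @param symbol A single IUPAC symbol.
#' @return Character vector of parent symbols, in canonical order.
#' @examples
#' character_parents("A")  # M R W
#' character_parents("N")  # none
#' @export
character_parents <- function(symbol) {
  symbol <- toupper(symbol)
  stopifnot(length(symbol) == 1)
  mask <- .mask_of(symbol)
  add <- c(1L, 2L, 4L, 8L)
  parents <- .IUPAC_SYMBOL_BY_MASK[bitwOr(mask, add[bitwAnd(mask, add) == 0L])]
  parents[order(match(parents, .IUPAC_CANONICAL))]
}

#' Compatibility of two IUPAC characters
#'
#' Two characters are compatible when they are identical or one base set is
#' included in the other (the matching rule used when aligning overlapping
#' motifs).
#'
#' @param c1,c2 Single IUPAC symbols.
#' @return `TRUE` or `FALSE`.
#' @examples
#' characters_compatible("G", "R")  # TRUE: {G} in {A,G}
#' characters_compatible("A", "S")  # FALSE
#' @export
characters_compatible <- function(c1, c2) {
  m1 <- .mask_of(toupper(c1))
  m2 <- .mask_of(toupper(c2))
  bitwAnd(m1, m2) == m1 || bitwAnd(m1, m2) == m2
}

.check_motif <- function(motif) {
  if (length(motif) != 1 || !is.character(motif) || is.na(motif) ||
      nchar(motif) < 1) {
    stop("motif must be a single non-empty IUPAC string", call. = FALSE)
  }
  chars <- strsplit(toupper(motif), "")[[1]]
  .mask_of(chars)  # errors on invalid characters
  chars
}

#' Exact instances of an IUPAC motif
#'
#' Enumerates the DNA words matching `motif`, i.e. the Cartesian product of
#' the per-position base sets. The motif `AWRT`, for instance, has the four
#' instances AAAT, AAGT, ATAT, ATGT.
#'
#' @param motif A single IUPAC motif string.
#' @return Character vector of instance L-mers, in alphabetical order.
#' @examples
#' motif_instances("AWRT")
#' @export
motif_instances <- function(motif) {
  chars <- .check_motif(motif)
  per_pos <- lapply(chars, iupac_letters)
  out <- do.call(expand.grid,
                 c(per_pos, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE))
  sort(do.call(paste0, out))
}

#' Match DNA words against an IUPAC motif
#'
#' @param word Character vector of DNA words over A,C,G,T, each the same
#'   length as `motif`.
#' @param motif A single IUPAC motif string.
#' @return Logical vector: `TRUE` where every base of the word belongs to
#'   the base set of the corresponding motif character.
#' @examples
#' motif_matches(c("AAGT", "ACGT"), "AWRT")
#' @export
motif_matches <- function(word, motif) {
  chars <- .check_motif(motif)
  word <- toupper(word)
  if (any(nchar(word) != length(chars))) {
    stop("word and motif lengths differ", call. = FALSE)
  }
  mmask <- .mask_of(chars)
  vapply(word, function(w) {
    b <- match(strsplit(w, "")[[1]], .BASES)
    if (anyNA(b)) {
      stop("words must be over A,C,G,T", call. = FALSE)
    }
    all(bitwAnd(mmask, bitwShiftL(1L, b - 1L)) > 0L)
  }, logical(1), USE.NAMES = FALSE)
}

#' Degeneracy summaries of an IUPAC motif
#'
#' `motif_degeneracy()` counts positions holding a degenerate character
#' (level 2 or more); `iupac_content()` sums the degeneracy levels over all
#' positions (between L and 4L); `instance_count()` multiplies them (the
#' number of exact instances).
#'
#' @param motif A single IUPAC motif string.
#' @return A single number.
#' @examples
#' motif_degeneracy("AWRT")  # 2
#' iupac_content("AWRT")     # 6
#' instance_count("AWRT")    # 4
#' @export
motif_degeneracy <- function(motif) {
  sum(iupac_level(.check_motif(motif)) >= 2L)
}

#' @rdname motif_degeneracy
#' @export
iupac_content <- function(motif) {
  sum(iupac_level(.check_motif(motif)))
}

#' @rdname motif_degeneracy
#' @export
instance_count <- function(motif) {
  prod(iupac_level(.check_motif(motif)))
}
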