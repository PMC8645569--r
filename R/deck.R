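#' Card suits and a standard deck
#'
#' `ocl_suits()` returns the four suit names in their canonical order;
#' `ocl_deck()` builds the standard 52-card deck as a tibble with one row per
#' card. Ranks run 1 (ace) to 13 (king).
#'
#' @return `ocl_deck()` returns a 52-row tibble with columns `rank` (integer
#'   1-13) and `suit` (factor with levels clubs, diamonds, hearts, spades).
#' @examples
#' ocl_deck()
#' @export
ocl_deck <- function() {
  tibble(
    rank = rep(1:13, times = 4L),
    suit = factor(rep(ocl_suits(), each = 13L), levels = ocl_suits())
  )
}

#' @rdname ocl_deck
#' @export
ocl_suits <- function() c("clubs", "diamonds", "hearts", "spades")

# single-letter suit codes used in CSV interchange
suit_to_letter <- function(suit) {
  c(clubs = "C", diamonds = "D", hearts = "H", spades = "S")[as.character(suit)]
}

letter_to_suit <- function(letter) {
  lookup <- c(C = "clubs", D = "diamonds", H = "hearts", S = "spades")
  out <- lookup[toupper(letter)]
  if (anyNA(out)) abort("Suit codes must be one of C, D, H, S.")
  factor(unname(out), levels = ocl_suits())
}

card_key <- function(rank, suit) paste(rank, as.character(suit))

check_deck <- function(deck) {
  if (!is.data.frame(deck) || !all(c("rank", "suit") %in% names(deck))) {
    abort("`deck` must be a data frame with columns `rank` and `suit`.")
  }
  keys <- card_key(deck$rank, deck$suit)
  if (nrow(deck) != 52L || anyDuplicated(keys) ||
      !all(deck$rank %in% 1:13) ||
      !all(as.character(deck$suit) %in% ocl_suits())) {
    abort("`deck` must contain the 52 distinct (rank, suit) cards.")
  }
  invisible(deck)
}
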