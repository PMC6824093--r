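#' Published per-species study counts
#'
#' The per-species counts printed for the original German Bight study:
#' birds tagged per autumn season (2017, 2018), birds subsequently detected,
#' and first flights per season and per route class. These are inputs for
#' consistency arithmetic (totals across species), not outputs of this
#' package's computations.
#'
#' @return Tibble with one row per species: `species`, `tagged_2017`,
#'   `tagged_2018`, `tagged_total`, `detected`, `flights_2017`,
#'   `flights_2018`, `alongshore`, `offshore`.
#' @export
thrush_study_counts <- function() {
  tibble(
    species = c("blackbird", "redwing", "song_thrush"),
    tagged_2017 = c(49, 14, 33),
    tagged_2018 = c(0, 34, 22),
    tagged_total = c(49, 48, 55),
    detected = c(19, 37, 44),
    flights_2017 = c(5, 2, 13),
    flights_2018 = c(0, 15, 14),
    alongshore = c(4, 10, 16),
    offshore = c(1, 7, 11)
  )
}

#' Totals of the published study counts
#'
#' Sums [thrush_study_counts()] across species: total birds tagged, first
#' flights analysed, and alongshore/offshore route totals.
#'
#' @return One-row tibble with `tagged_birds`, `flights_analysed`,
#'   `alongshore`, `offshore`.
#' @export
summarise_study_counts <- function() {
  counts <- thrush_study_counts()
  tibble(
    tagged_birds = sum(counts$tagged_total),
    flights_analysed = sum(counts$flights_2017 + counts$flights_2018),
    alongshore = sum(counts$alongshore),
    offshore = sum(counts$offshore)
  )
}
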