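# Worked-example fixtures: the printed profiles and their expected
# values, plus a seeded random-profile generator.

#' Worked-example fixtures
#'
#' Returns the bundle of profiles used throughout the documentation and
#' tests, together with their expected values: the four-taxon profile
#' (12, 6, 6, 5); the Viola profile (9, 7, 7, 4, 4, 4, 2, 2, 2, 2, 2, 1);
#' the strictly simple heads 15, 9, 265 and 47 with the hybrid counts of
#' their B/D realizations; (8, 2); (5, 1); and (2, 1, 1, 1).  When `dir`
#' is given, each profile is also written as a TSV file and the expected
#' values as JSON.
#'
#' @param dir optional directory to write `*.tsv` fixture files plus
#'   `expected.json` into.
#' @return a named list of entries, each with `profile` and `expect`
#'   (named list of expected numbers).
#' @export
fixtures <- function(dir = NULL) {
  viola_labels <- c("langsdorffii", "tracheliifolia", "grahamii",
                    "palustris721", "blanda", "palustris933", "glabella",
                    "macloskeyi", "repens", "verecunda", "Viola", "Rubellium")
  fx <- list(
    intro_12665 = list(
      profile = ploidy_profile(c(12, 6, 6, 5)),
      expect = list(h = 5, s = 4, c = 2,
                    sigma = list(c(12, 6, 6, 5), c(6, 6, 6, 5), c(6, 6, 5),
                                 c(6, 5), c(5, 1)))),
    viola = list(
      profile = ploidy_profile(c(9, 7, 7, 4, 4, 4, 2, 2, 2, 2, 2, 1),
                               viola_labels),
      expect = list(h = 5, s = 12, c = 4, terminal = c(2, 1, 1, 1),
                    terminal_h = 1)),
    fig6_15 = list(profile = ploidy_profile(15),
                   expect = list(h_B = 6, h_D = 5)),
    fig6_9 = list(profile = ploidy_profile(9),
                  expect = list(h_B = 4, h_D = 4)),
    fig6_265 = list(profile = ploidy_profile(265),
                    expect = list(h_B = 10, h_D = 11)),
    fig6_47 = list(profile = ploidy_profile(47),
                   expect = list(h_B = 9, h_search = 8)),
    line8_82 = list(profile = ploidy_profile(c(8, 2)),
                    expect = list(h = 3, traceback_h = 4, line8 = TRUE)),
    simple_51 = list(profile = ploidy_profile(c(5, 1)),
                     expect = list(h = 3, vertices_B = 9)),
    terminal_2111 = list(profile = ploidy_profile(c(2, 1, 1, 1)),
                         expect = list(h = 1))
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (nm in names(fx)) {
      write_profile(fx[[nm]]$profile, file.path(dir, paste0(nm, ".tsv")))
    }
    jsonlite::write_json(lapply(fx, `[[`, "expect"),
                         file.path(dir, "expected.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  fx
}
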