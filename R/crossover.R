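# run code under a local RNG seed without touching global RNG state
with_seed <- function(seed, code) {
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = genv)), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Default algorithm labels
#'
#' The three propagation arms: a contour-guided deformable registration, a
#' hybrid intensity-plus-structure deformable registration, and a rigid 1:1
#' copy.
#' @return Character vector of length 3.
#' @export
algorithm_labels <- function() c("contour_dir", "hybrid_dir", "rigid_copy")

#' Generate a carryover-balanced cross-over schedule
#'
#' Each physician reviews every case once per session, under a different
#' algorithm each session, so that every (physician, case, algorithm) triple
#' occurs exactly once across the sessions. Algorithm sequences over the
#' sessions are drawn from the full set of permutations of the algorithms (a
#' Williams-type balanced set for three treatments), cycled over the
#' (physician, case) cells so that first-order carryover counts are as
#' balanced as the cell count allows. Presentation order within each session
#' is randomly permuted from the seed.
#'
#' @param n_physicians Number of physicians (default 13).
#' @param n_cases Number of cases per session (default 10).
#' @param algorithms Algorithm labels; their number must equal `sessions`.
#' @param sessions Number of sessions (default 3).
#' @param seed Integer seed; the schedule is a deterministic function of it.
#' @return A tibble of class `crossover_schedule` with columns
#'   `physician_id`, `session`, `order_in_session`, `case_id`, `algorithm`,
#'   `preceding_algorithm` (the algorithm under which the same physician saw
#'   the same case in the previous session; `NA` in session 1).
#' @export
generate_crossover <- function(n_physicians = 13, n_cases = 10,
                               algorithms = algorithm_labels(),
                               sessions = 3, seed = 1) {
  if (length(algorithms) != sessions) {
    abort_domain("unsupported design: `sessions` must equal the number of algorithms")
  }
  perms <- all_permutations(seq_along(algorithms))
  physicians <- sprintf("P%02d", seq_len(n_physicians))
  cases <- sprintf("C%02d", seq_len(n_cases))
  # sequence assignment: global cycling over (physician, case) cells
  cells <- tidyr::expand_grid(physician_id = physicians, case_id = cases)
  cells$seq_idx <- (seq_len(nrow(cells)) - 1L) %% nrow(perms) + 1L
  long <- purrr::pmap_dfr(cells, function(physician_id, case_id, seq_idx) {
    tibble::tibble(physician_id = physician_id, case_id = case_id,
                   session = seq_len(sessions),
                   algorithm = algorithms[perms[seq_idx, ]])
  })
  long <- long |>
    dplyr::group_by(.data$physician_id, .data$case_id) |>
    dplyr::arrange(.data$session, .by_group = TRUE) |>
    dplyr::mutate(preceding_algorithm = dplyr::lag(.data$algorithm)) |>
    dplyr::ungroup()
  # presentation order within each physician-session
  sched <- with_seed(seed, {
    long |>
      dplyr::group_by(.data$physician_id, .data$session) |>
      dplyr::mutate(order_in_session = sample(dplyr::n())) |>
      dplyr::ungroup()
  })
  sched <- sched |>
    dplyr::arrange(.data$physician_id, .data$session, .data$order_in_session) |>
    dplyr::select(dplyr::all_of(c("physician_id", "session", "order_in_session",
                                  "case_id", "algorithm", "preceding_algorithm")))
  class(sched) <- c("crossover_schedule", class(sched))
  attr(sched, "seed") <- seed
  attr(sched, "algorithms") <- algorithms
  sched
}

# all permutations of a vector, in lexicographic order
all_permutations <- function(x) {
  n <- length(x)
  if (n == 1L) return(matrix(x, 1, 1))
  out <- NULL
  for (i in seq_len(n)) {
    rest <- all_permutations(x[-i])
    out <- rbind(out, cbind(x[i], rest))
  }
  out
}

#' First-order carryover count matrix of a schedule
#'
#' Counts, over (physician, case) cells, how often a presentation under one
#' algorithm was preceded (in the previous session) by each other algorithm.
#'
#' @param schedule A [generate_crossover()] schedule.
#' @return A matrix: rows = current algorithm, columns = preceding algorithm.
#' @export
carryover_matrix <- function(schedule) {
  algorithms <- attr(schedule, "algorithms") %||% sort(unique(schedule$algorithm))
  tr <- dplyr::filter(schedule, !is.na(.data$preceding_algorithm))
  m <- table(factor(tr$algorithm, levels = algorithms),
             factor(tr$preceding_algorithm, levels = algorithms))
  unclass(m)
}
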