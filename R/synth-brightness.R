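brightness_stimuli <- c("glare", "nonglare", "isoluminant")

#' Generate brightness-comparison choice records
#'
#' Emulates the two-alternative-plus-equal brightness judgement task: the
#' three stimuli (glare, nonglare, isoluminant) are compared pairwise,
#' `n_per_pair` trials per pairing, and on each trial the response is
#' `"first-brighter"`, `"second-brighter"` or `"equal"`. Choices follow a
#' softmax rule over the latent brightness weights with temperature
#' `margin`; with `margin = 0` the rule is the deterministic argmax (strict
#' weight order decides, exact ties give `"equal"`).
#'
#' @param weights Named numeric brightness strengths for exactly the three
#'   stimuli `glare`, `nonglare`, `isoluminant`.
#' @param n_per_pair Trials per pairing (>= 1); the task used 10.
#' @param margin Softmax temperature; 0 for deterministic responses.
#' @param seed Seed for the stochastic rule.
#' @return Tibble with `trial`, `stim_first`, `stim_second`, `choice`.
#' @export
generate_brightness_responses <- function(weights, n_per_pair = 10,
                                          margin = 0, seed = 1) {
  if (is.null(names(weights)) || !setequal(names(weights), brightness_stimuli)) {
    rlang::abort(paste("`weights` must name exactly:",
                       paste(brightness_stimuli, collapse = ", ")),
                 class = "oculaware_config_error")
  }
  stopifnot(n_per_pair >= 1, margin >= 0)
  pairs <- list(c("glare", "nonglare"), c("glare", "isoluminant"),
                c("nonglare", "isoluminant"))
  set.seed(as.integer(seed))
  rows <- purrr::map(pairs, function(p) {
    w1 <- weights[[p[1]]]; w2 <- weights[[p[2]]]
    choice <- character(n_per_pair)
    for (i in seq_len(n_per_pair)) {
      if (margin == 0) {
        choice[i] <- if (w1 > w2) "first-brighter"
                     else if (w2 > w1) "second-brighter"
                     else "equal"
      } else {
        s <- c(w1, w2, (w1 + w2) / 2) / margin
        pr <- exp(s - max(s)); pr <- pr / sum(pr)
        choice[i] <- sample(c("first-brighter", "second-brighter", "equal"),
                            1, prob = pr)
      }
    }
    tibble::tibble(stim_first = p[1], stim_second = p[2], choice = choice)
  })
  out <- dplyr::bind_rows(rows)
  out$trial <- seq_len(nrow(out))
  dplyr::relocate(out, "trial")
}
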