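# Small fixtures shared across test files; everything is built in code.

# a stream with a single planted rectangular block of constant value
planted_block_stream <- function(n_time = 80L, n_loc = 60L,
                                 t_range = c(30L, 41L),
                                 loc_range = c(20L, 29L),
                                 value = 10, seed = 42L) {
  withr::with_seed(seed, {
    values <- matrix(rnorm(n_time * n_loc), nrow = n_time)
    mask <- matrix(0L, n_time, n_loc)
    ti <- seq.int(t_range[1], t_range[2])
    li <- seq.int(loc_range[1], loc_range[2])
    values[ti, li] <- value
    mask[ti, li] <- 1L
    registry <- tibble::tibble(event_id = 1L, class = "A", shape_id = 1L,
                               start_time = t_range[1],
                               duration = length(ti),
                               max_width = length(li),
                               centre_loc = as.integer(round(mean(li))))
    ccstream:::new_labeled_stream(values, mask, registry, NULL)
  })
}

# observation table from a known age-varying logistic model
simulated_obs_table <- function(N = 150L, ages = c(8L, 16L, 24L, 32L),
                                drift = 0.2, seed = 7L) {
  withr::with_seed(seed, {
    rows <- lapply(seq_along(ages), function(j) {
      x1 <- rnorm(N); x2 <- rnorm(N)
      eta <- -0.2 + (0.5 + drift * j) * x1 - (0.3 + drift / 2 * j) * x2
      tibble::tibble(event_id = seq_len(N), age = ages[j],
                     label = rbinom(N, 1L, plogis(eta)), f1 = x1, f2 = x2)
    })
    dplyr::bind_rows(rows)
  })
}

# hand-built 3 x 2 rectangular event with per-time means (2, 3.5, 5)
rect_event_pixels <- function() {
  tibble::tibble(t = rep(1:3, each = 2), loc = rep(1:2, times = 3),
                 value = c(1, 3, 3, 4, 4, 6))
}
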