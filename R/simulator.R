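#' Specify a simulation scenario
#'
#' A scenario fixes the shape of the generating model — alphabet size,
#' order, number of parts — and the experimental design: sample sizes,
#' replicate count, seed, the minimum total-variation separation `delta`
#' between distinct part rows, and the Dirichlet concentration used to draw
#' the rows.
#'
#' @param alphabet_size `|A|` (>= 2).
#' @param order Memory order `o`.
#' @param n_parts Number of parts `|L| <= |A|^o`.
#' @param sample_sizes Integer vector of sequence lengths to simulate.
#' @param replicates Replicates per sample size (`R >= 1`).
#' @param seed Integer seed driving every random draw of the scenario.
#' @param separation Minimum pairwise total-variation distance between part
#'   rows, in `[0, 1)`. Zero imposes no constraint beyond distinctness.
#' @param concentration Dirichlet concentration for row generation.
#' @param block_size Block size used when coding data in experiments.
#' @param label Optional scenario label for result tables.
#' @return Object of class `pmm_scenario`.
#' @export
scenario_spec <- function(alphabet_size, order, n_parts, sample_sizes,
                          replicates = 1L, seed = 1L, separation = 0,
                          concentration = 1, block_size = 4L,
                          label = NULL) {
  if (n_parts > alphabet_size^order) {
    stop("`n_parts` cannot exceed the number of states", call. = FALSE)
  }
  if (separation < 0 || separation >= 1) {
    stop("`separation` must lie in [0, 1)", call. = FALSE)
  }
  if (replicates < 1L) stop("`replicates` must be >= 1", call. = FALSE)
  structure(
    list(alphabet_size = as.integer(alphabet_size),
         order = as.integer(order), n_parts = as.integer(n_parts),
         sample_sizes = as.integer(sample_sizes),
         replicates = as.integer(replicates), seed = as.integer(seed),
         separation = separation, concentration = concentration,
         block_size = as.integer(block_size),
         label = label %||% sprintf("A%d_o%d_L%d", alphabet_size, order,
                                    n_parts)),
    class = "pmm_scenario"
  )
}

default_alphabet <- function(m) {
  pool <- c(letters, as.character(0:9))
  if (m == 2L) alphabet(c("0", "1")) else
    if (m == 4L) alphabet(c("a", "c", "g", "t")) else
      alphabet(pool[seq_len(m)])
}

rdirichlet_row <- function(m, concentration) {
  g <- stats::rgamma(m, shape = concentration)
  if (sum(g) == 0) g <- rep(1, m)
  g / sum(g)
}

tv_distance <- function(p, q) sum(abs(p - q)) / 2

#' Draw a random partition Markov model
#'
#' States are split into `n_parts` balanced parts by a seeded shuffle; each
#' part's conditional row is drawn from a Dirichlet and the whole set is
#' redrawn until every pair of rows is at least `separation` apart in total
#' variation (so the model is minimal).
#'
#' @param scenario A [scenario_spec()].
#' @param max_tries Redraw budget for meeting the separation constraint.
#' @return A [pmm()] (without part weights: the stationary law is not
#'   computed).
#' @export
random_pmm <- function(scenario, max_tries = 1000L) {
  set.seed(scenario$seed)
  m <- scenario$alphabet_size
  ab <- default_alphabet(m)
  spec <- model_spec(scenario$order, block_size = scenario$block_size)
  states <- enumerate_states(ab, spec)
  S <- length(states)
  K <- scenario$n_parts
  sizes <- rep(S %/% K, K)
  extra <- S %% K
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  labels <- rep(seq_len(K), times = sizes)[sample.int(S)]
  part <- partition(labels, states)
  for (try in seq_len(max_tries)) {
    rows <- t(vapply(seq_len(K), function(i)
      rdirichlet_row(m, scenario$concentration), numeric(m)))
    ok <- TRUE
    if (K > 1L) {
      for (i in seq_len(K - 1L)) {
        for (j in (i + 1L):K) {
          d <- tv_distance(rows[i, ], rows[j, ])
          if (d < scenario$separation || d == 0) {
            ok <- FALSE
            break
          }
        }
        if (!ok) break
      }
    }
    if (ok) {
      return(pmm(ab, spec, part, rows))
    }
  }
  stop("could not achieve the requested row separation", call. = FALSE)
}

#' Sample a sequence from a partition Markov model
#'
#' The chain is started from a uniformly drawn state, run for a burn-in
#' that is discarded (to approximate stationarity), and then sampled for
#' exactly `n` symbols, each drawn from the conditional law of the part of
#' the current state.
#'
#' @param pmm A [pmm()].
#' @param n Output length (`> o`, or `> G` for gapped models).
#' @param seed Optional seed.
#' @param burn_in Discarded prefix length; defaults to `10 * |S|`.
#' @return Character vector of `n` symbols.
#' @export
sample_sequence <- function(pmm, n, seed = NULL, burn_in = NULL) {
  if (!is.null(seed)) set.seed(seed)
  spec <- pmm$spec
  h <- history_length(spec)
  if (n <= h) stop("`n` must exceed the model history", call. = FALSE)
  m <- length(pmm$alphabet)
  S <- length(pmm$states)
  if (is.null(burn_in)) burn_in <- 10L * S
  total <- n + burn_in
  # cumulative conditional laws per state
  cum <- t(apply(state_probs(pmm), 1L, cumsum))
  o <- spec$order
  k <- state_tuple_length(spec)
  gap <- spec$gap
  xi <- integer(total)
  xi[seq_len(h)] <- sample.int(m, h, replace = TRUE)
  u <- stats::runif(total - h)
  if (is.null(gap)) {
    sid <- 1L
    for (j in seq_len(o)) sid <- sid + (xi[j] - 1L) * m^(o - j)
    mo <- m^(o - 1L)
    for (t in (h + 1L):total) {
      a <- findInterval(u[t - h], cum[sid, ]) + 1L
      if (a > m) a <- m
      xi[t] <- a
      sid <- ((sid - 1L) %% mo) * m + a
    }
  } else {
    for (t in (h + 1L):total) {
      id <- 1L + (xi[t - gap] - 1L) * m^o
      for (j in seq_len(o)) id <- id + (xi[t - o + j - 1L] - 1L) * m^(o - j)
      a <- findInterval(u[t - h], cum[id, ]) + 1L
      if (a > m) a <- m
      xi[t] <- a
    }
  }
  as.character(pmm$alphabet)[xi[(burn_in + 1L):total]]
}

#' Compare by-states and by-parts compression on simulated data
#'
#' Draws one generating model per scenario, then for every sample size and
#' replicate simulates a sequence, fits both serialisation strategies (full
#' chain by states; BIC-estimated PMM by parts), assembles containers under
#' the classical accounting, and records the per-field bit costs and
#' compression ratio.
#'
#' @param scenario A [scenario_spec()].
#' @param accounting Accounting convention for the containers.
#' @return A tibble with one row per (sample size, replicate, method):
#'   columns `label`, `n`, `replicate`, `method`, `model_bits`,
#'   `data_bits`, `total_bits`, `rc`. The generating model and per-replicate
#'   seeds are attached as attributes `model` and `manifest`.
#' @export
run_comparison <- function(scenario, accounting = "paper") {
  model <- random_pmm(scenario)
  ab <- model$alphabet
  o <- scenario$order
  b <- scenario$block_size
  rows <- list()
  manifest <- list()
  for (n in scenario$sample_sizes) {
    for (r in seq_len(scenario$replicates)) {
      seed <- scenario$seed + 7919L * match(n, scenario$sample_sizes) + r
      x <- sample_sequence(model, n, seed = seed)
      counts <- suppressWarnings(
        count_transitions(x, ab, model_spec(o, block_size = b)))
      part <- estimate_partition(counts)
      warn <- o >= floor(log(n, base = length(ab))) - 1
      for (method in c("states", "parts")) {
        cont <- assemble_container(
          counts, x = x, mode = method, accounting = accounting, b = b,
          partition = if (method == "parts") part else NULL,
          desc_mode = "escape")
        rows[[length(rows) + 1L]] <- tibble::tibble(
          label = scenario$label, n = n, replicate = r,
          method = cont$mode, model_bits = cont$model_bits,
          data_bits = cont$data_bits, total_bits = cont$total_bits,
          rc = cont$compression_ratio, order_warning = warn)
      }
      manifest[[length(manifest) + 1L]] <- list(n = n, replicate = r,
                                                seed = seed)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "model") <- model
  attr(out, "manifest") <- manifest
  attr(out, "uncompressed_bits_per_symbol") <-
    floor(log2(max(length(ab) - 1, 1))) + 1
  class(out) <- c("pmm_comparison", class(out))
  out
}

#' Summarise a comparison run
#'
#' Means over replicates per (sample size, method). Because it is ambiguous
#' whether a mean compression ratio should average per-replicate ratios or
#' divide mean sizes, both are reported (`rc_mean` and `rc_of_means`).
#'
#' @param results Tibble from [run_comparison()].
#' @return A tibble with one row per (label, n, method).
#' @export
summarize_comparison <- function(results) {
  per_sym <- attr(results, "uncompressed_bits_per_symbol", exact = TRUE) %||% 1
  results <- tibble::as_tibble(results)
  key <- interaction(results$label, results$n, results$method, drop = TRUE)
  parts <- split(results, key)
  out <- lapply(parts, function(d) {
    tibble::tibble(
      label = d$label[1L], n = d$n[1L], method = d$method[1L],
      replicates = nrow(d),
      model_bits = mean(d$model_bits),
      data_bits = mean(d$data_bits),
      total_bits = mean(d$total_bits),
      rc_mean = mean(d$rc),
      rc_of_means = d$n[1L] * per_sym / mean(d$total_bits)
    )
  })
  res <- do.call(rbind, out)
  res[order(res$label, res$n, res$method), ]
}

#' Plot a by-states versus by-parts comparison
#'
#' Mean total bits per sample size and method.
#'
#' @param object Tibble from [run_comparison()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pmm_comparison <- function(object, ...) {
  s <- summarize_comparison(object)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$n, y = .data$total_bits,
                                  colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "sample size n", y = "mean total bits",
                  colour = NULL, title = "Compression cost by strategy") +
    ggplot2::theme_minimal()
}
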