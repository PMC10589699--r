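#' Agent-population experiment configuration
#'
#' @param agent_condition `"aoa"` (concepts sampled from children's
#'   acquisition probabilities), `"control"` (uniform sampling) or
#'   `"generative"` (sampling from a trained internal model; see
#'   [train_agent()]).
#' @param probe_conditions subset of `c("aoa", "unconstrained")`: probe pairs
#'   drawn from the unacquired AoA concepts, or from all unacquired concepts.
#' @param n_agents number of simulated agents (default 100).
#' @param probes_per_month forced-choice probe pairs per month per probe
#'   condition (default 50).
#' @param seed master seed; per-agent streams are derived from it.
#' @param control_pool `"non_aoa"` restricts control agents to concepts
#'   outside the AoA set; `"full"` samples from the whole vocabulary.
#' @param ci_method `"normal"` (mean +/- 1.96 SEM) or `"percentile"` across
#'   agents.
#' @return A list of class `agent_config`.
#' @export
agent_config <- function(agent_condition = c("aoa", "control", "generative"),
                         probe_conditions = c("aoa", "unconstrained"),
                         n_agents = 100, probes_per_month = 50, seed = 1,
                         control_pool = c("non_aoa", "full"),
                         ci_method = c("normal", "percentile")) {
  agent_condition <- match.arg(agent_condition)
  stopifnot(all(probe_conditions %in% c("aoa", "unconstrained")),
            length(probe_conditions) >= 1, n_agents >= 1, probes_per_month >= 1)
  structure(list(agent_condition = agent_condition,
                 probe_conditions = probe_conditions,
                 n_agents = as.integer(n_agents),
                 probes_per_month = as.integer(probes_per_month),
                 seed = as.integer(seed),
                 control_pool = match.arg(control_pool),
                 ci_method = match.arg(ci_method)),
            class = "agent_config")
}

#' Simulate one agent's month-by-month knowledge-state trajectory
#'
#' AoA agents add concepts one at a time, each sampled from the normalized
#' acquisition probabilities over unacquired AoA concepts
#' ([acquisition_distribution()]); control agents sample uniformly without
#' replacement from the eligible pool.
#'
#' @param condition `"aoa"` or `"control"`.
#' @param schedule a [month_schedule()].
#' @param world a [build_world()] world (control agents need its vocabulary;
#'   AoA agents its table).
#' @param seed optional seed; when `NULL` the current RNG stream is used.
#' @param control_pool see [agent_config()].
#' @return A list of character vectors, one cumulative knowledge state per
#'   month (sizes equal to the schedule's cumulative counts).
#' @export
simulate_trajectory <- function(condition = c("aoa", "control"), schedule,
                                world, seed = NULL,
                                control_pool = "non_aoa") {
  condition <- match.arg(condition)
  stopifnot(inherits(schedule, "month_schedule"), inherits(world, "world"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  vocab <- world$pair$shared_concepts
  pool0 <- if (condition == "aoa") {
    if (is.null(world$table)) stop("aoa condition needs an acquisition table")
    world$table$concepts
  } else if (control_pool == "non_aoa") {
    setdiff(vocab, world$aoa_concepts)
  } else vocab
  known <- character(0)
  states <- vector("list", length(schedule$months))
  for (mi in seq_along(schedule$months)) {
    need <- schedule$n_m[mi]
    if (length(setdiff(pool0, known)) < need) {
      stop("eligible pool exhausted in month ", schedule$months[mi])
    }
    if (condition == "aoa") {
      for (slot in seq_len(need)) {
        p <- suppressWarnings(
          acquisition_distribution(world$table, schedule$months[mi], known))
        known <- c(known, sample(names(p), 1, prob = p))
      }
    } else if (need > 0) {
      known <- c(known, sample(setdiff(pool0, known), need))
    }
    states[[mi]] <- known
  }
  names(states) <- as.character(schedule$months)
  states
}

#' Sample forced-choice probe pairs
#'
#' Pairs are drawn independently (a concept may recur across pairs); each
#' pair is two distinct concepts from the eligible pool.
#'
#' @param condition `"aoa"` (pool = unacquired AoA concepts) or
#'   `"unconstrained"` (pool = all unacquired concepts).
#' @param state current knowledge state.
#' @param world a [build_world()] world.
#' @param k number of pairs.
#' @param seed optional seed.
#' @return A k x 2 character matrix, one probe pair per row.
#' @export
sample_probes <- function(condition = c("aoa", "unconstrained"), state, world,
                          k = 1, seed = NULL) {
  condition <- match.arg(condition)
  stopifnot(inherits(world, "world"), k >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  pool <- if (condition == "aoa") {
    setdiff(world$aoa_concepts, state)
  } else {
    setdiff(world$pair$shared_concepts, state)
  }
  if (length(pool) < 2) stop("probe pool has fewer than 2 eligible concepts")
  t(vapply(seq_len(k), function(i) sample(pool, 2), character(2)))
}

#' Run the forced-choice experiment over a population of agents
#'
#' For each agent: simulate a knowledge-state trajectory under the agent
#' condition, then at each month evaluate `probes_per_month` forced choices
#' under each probe condition. Fully reproducible for a fixed seed.
#'
#' @param config an [agent_config()].
#' @param world a [build_world()] world with an acquisition table.
#' @param schedule a [month_schedule()]; defaults to [monthly_counts()] of
#'   the world's table.
#' @param model an `internal_model` (required for the `"generative"` agent
#'   condition; see [train_agent()]).
#' @return An object of class `trajectory_result`: `per_agent` (data frame
#'   with one row per agent x month x probe condition, giving `accuracy` and
#'   `n_ties`), `summary` (per month x probe condition mean and 95 percent
#'   CI across agents) and the `config`.
#' @export
run_experiment <- function(config, world, schedule = NULL, model = NULL) {
  stopifnot(inherits(config, "agent_config"), inherits(world, "world"))
  schedule <- schedule %||% monthly_counts(world$table)
  seeds <- spawn_seeds(config$seed, config$n_agents)
  rows <- vector("list", 0)
  for (a in seq_len(config$n_agents)) {
    set.seed(seeds[a])
    states <- if (config$agent_condition == "generative") {
      if (is.null(model)) stop("generative condition needs a trained internal model")
      generate_sequence(model, schedule, world)
    } else {
      simulate_trajectory(config$agent_condition, schedule, world,
                          control_pool = config$control_pool)
    }
    for (mi in seq_along(schedule$months)) {
      state <- states[[mi]]
      if (length(state) < 2) next
      for (pc in config$probe_conditions) {
        probes <- sample_probes(pc, state, world, k = config$probes_per_month)
        res <- apply(probes, 1, function(pr) {
          fc <- forced_choice(world, state, pr)
          c(correct = fc$chosen_mapping == "correct", tie = fc$tie_broken)
        })
        rows[[length(rows) + 1]] <- data.frame(
          agent = a, month = schedule$months[mi], probe_condition = pc,
          accuracy = mean(res["correct", ]), n_ties = sum(res["tie", ]))
      }
    }
  }
  per_agent <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(
    split(per_agent, list(per_agent$month, per_agent$probe_condition), drop = TRUE),
    function(d) {
      m <- mean(d$accuracy)
      if (config$ci_method == "normal") {
        sem <- stats::sd(d$accuracy) / sqrt(nrow(d))
        lo <- m - 1.96 * sem; hi <- m + 1.96 * sem
      } else {
        q <- stats::quantile(d$accuracy, c(0.025, 0.975), names = FALSE)
        lo <- q[1]; hi <- q[2]
      }
      data.frame(month = d$month[1], probe_condition = d$probe_condition[1],
                 mean_accuracy = m, ci_lo = min(lo, m), ci_hi = max(hi, m),
                 n_agents = nrow(d))
    }))
  summary <- summary[order(summary$probe_condition, summary$month), ]
  rownames(summary) <- NULL
  structure(list(per_agent = per_agent, summary = summary, config = config),
            class = "trajectory_result")
}

#' @export
print.trajectory_result <- function(x, ...) {
  cat(sprintf("<trajectory_result: %s agents (n=%d), %d month x probe cells>\n",
              x$config$agent_condition, x$config$n_agents, nrow(x$summary)))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Write a trajectory result as tidy CSVs
#'
#' Writes `<stem>_per_agent.csv` and `<stem>_summary.csv`.
#'
#' @param result a [run_experiment()] result.
#' @param stem output path stem.
#' @return Invisibly, the two paths.
#' @export
write_trajectory_csv <- function(result, stem) {
  stopifnot(inherits(result, "trajectory_result"))
  paths <- paste0(stem, c("_per_agent.csv", "_summary.csv"))
  utils::write.csv(result$per_agent, paths[1], row.names = FALSE)
  utils::write.csv(result$summary, paths[2], row.names = FALSE)
  invisible(paths)
}
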