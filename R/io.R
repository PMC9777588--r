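#' Read and write chain JSON
#'
#' The chain file format is
#' `{"states": [...], "beta": x, "p0": [...], "matrices": [[[...]]],
#' "convention": "to_from"|"from_to"}` with the matrices listed in time order
#' `M1..MN`. `"to_from"` (the default) stores column-stochastic matrices as
#' lists of rows; `"from_to"` stores row-stochastic matrices, transposed on
#' read. Readers validate on load; a reversed chain serializes like any
#' other.
#'
#' @param path file path.
#' @return `read_chain_json()` returns a [driven_chain()];
#'   `write_chain_json()` returns `path` invisibly.
#' @export
read_chain_json <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  convention <- spec$convention %||% "to_from"
  mats <- spec$matrices
  if (is.array(mats) && length(dim(mats)) == 3) {
    mats <- lapply(seq_len(dim(mats)[1]), function(i) mats[i, , ])
  } else if (is.matrix(mats)) {
    mats <- list(mats)
  } else if (is.list(mats)) {
    mats <- lapply(mats, function(m) do.call(rbind, lapply(m, as.numeric)))
  }
  driven_chain(spec$states, spec$p0, mats, beta = spec$beta,
               convention = convention)
}

#' @rdname read_chain_json
#' @param chain a [driven_chain()].
#' @export
write_chain_json <- function(chain, path) {
  spec <- list(
    states = chain$states,
    beta = chain$beta,
    p0 = unname(chain$p0),
    matrices = lapply(chain$matrices, function(M) {
      lapply(seq_len(nrow(M)), function(i) unname(M[i, ]))
    }),
    convention = "to_from"
  )
  jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read and write energy-family JSON
#'
#' Format: `{"beta": x, "energies": [[...], ...], "gauges": [...]}`, energies
#' aligned with the chain file's state order, one vector per step `E0..EN`.
#'
#' @param path file path.
#' @param states state labels the energies refer to.
#' @return `read_energy_json()` returns an `energy_family`.
#' @export
read_energy_json <- function(path, states) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  energies <- spec$energies
  if (is.matrix(energies)) {
    energies <- lapply(seq_len(nrow(energies)), function(i) energies[i, ])
  }
  gauges <- spec$gauges %||% rep(0, length(energies))
  new_energy_family(energies, as.numeric(spec$beta), gauges,
                    as.character(states))
}

#' @rdname read_energy_json
#' @param family an [energy_family()].
#' @export
write_energy_json <- function(family, path) {
  spec <- list(
    beta = family$beta,
    energies = lapply(family$energies, unname),
    gauges = family$gauges
  )
  jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read and write trajectory CSV
#'
#' Columns `step` (0-based) and `state`; multiple trajectories may share a
#' file with an optional `trajectory` id column.
#'
#' @param path file path.
#' @return a character vector of states (single trajectory), or a list of
#'   them keyed by trajectory id.
#' @export
read_trajectory_csv <- function(path) {
  d <- utils::read.csv(path, colClasses = "character")
  if (!all(c("step", "state") %in% names(d))) {
    abort("trajectory CSV needs columns 'step' and 'state'")
  }
  d$step <- as.integer(d$step)
  if ("trajectory" %in% names(d)) {
    out <- lapply(split(d, d$trajectory), function(g) g$state[order(g$step)])
    return(out)
  }
  d$state[order(d$step)]
}

#' @rdname read_trajectory_csv
#' @param x a vector of state labels.
#' @export
write_trajectory_csv <- function(x, path) {
  utils::write.csv(
    data.frame(step = seq_along(x) - 1, state = as.character(x)),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Write a Crooks report as TSV
#'
#' Columns `work`, `prob_forward`, `prob_backward`, `observed_ratio`,
#' `predicted_ratio`, `defined`.
#'
#' @param report a [crooks_report()].
#' @param path file path.
#' @export
write_crooks_tsv <- function(report, path) {
  d <- report$table
  out <- data.frame(
    work = d$work,
    prob_forward = d$p_forward,
    prob_backward = d$p_backward,
    observed_ratio = d$observed_ratio,
    predicted_ratio = d$predicted_ratio,
    defined = d$defined
  )
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write adaptation-protocol JSON
#'
#' Format: `{"states": [...], "beta": x, "environments":
#' [{"utility": [...], "dwell": n}, ...], "learner": {"proposal":
#' "uniform"|"always_swap"}, "seed": n}`.
#'
#' @param path file path.
#' @return an [adaptation_protocol()].
#' @export
read_protocol_json <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  envs <- spec$environments
  if (is.data.frame(envs)) {
    envs <- lapply(seq_len(nrow(envs)), function(i) {
      decision_environment(unlist(envs$utility[i]), envs$dwell[i] %||% 1L)
    })
  } else {
    envs <- lapply(envs, function(e) {
      decision_environment(as.numeric(e$utility), e$dwell %||% 1L)
    })
  }
  adaptation_protocol(
    states = spec$states, beta = spec$beta, environments = envs,
    proposal = spec$learner$proposal %||% "uniform",
    seed = spec$seed %||% 1L
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
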