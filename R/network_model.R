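#' Construct a validated reaction network
#'
#' A reaction network is the system under study: species (molecule counts,
#' dimensionless), strictly positive parameters, and reactions carrying an
#' integer net stoichiometry and a rate-law expression over the declared
#' identifiers. Networks are either Markov jump processes (propensities define
#' the intrinsic noise) or Langevin systems carrying an explicit constant
#' diffusion matrix.
#'
#' @param species named numeric vector of initial amounts, or a data.frame with
#'   columns `id`, `initial_amount` and optionally `is_boundary`.
#' @param parameters named numeric vector of strictly positive parameter values.
#' @param reactions list; each element a list with `id`, `stoich` (named numeric
#'   vector of integer net changes over species) and `rate` (character rate law).
#' @param kind `"markov-jump"` or `"langevin"`.
#' @param boundary character vector of boundary species ids (fixed amounts,
#'   excluded from the dynamics; may still appear in rate laws). Ignored when
#'   `species` is a data.frame with an `is_boundary` column.
#' @param diffusion for Langevin networks: symmetric diffusion matrix over the
#'   dynamic species (count^2 / time).
#' @param rate_parameters character vector of the parameters that scale reaction
#'   rates linearly (the set over which summation theorems hold); defaults to
#'   all parameters.
#' @param name model name used in reports.
#' @return an object of class `reaction_network`.
#' @export
#' @examples
#' net <- reaction_network(
#'   species = c(X = 5),
#'   parameters = c(k_s = 2, k_d = 0.4),
#'   reactions = list(
#'     list(id = "synthesis", stoich = c(X = 1), rate = "k_s"),
#'     list(id = "degradation", stoich = c(X = -1), rate = "k_d * X")
#'   )
#' )
reaction_network <- function(species, parameters, reactions,
                             kind = c("markov-jump", "langevin"),
                             boundary = character(),
                             diffusion = NULL,
                             rate_parameters = NULL,
                             name = "network") {
  kind <- match.arg(kind)

  if (is.data.frame(species)) {
    sp <- data.frame(
      id = as.character(species$id),
      initial_amount = as.numeric(species$initial_amount),
      is_boundary = if ("is_boundary" %in% names(species)) {
        as.logical(species$is_boundary)
      } else {
        as.character(species$id) %in% boundary
      },
      stringsAsFactors = FALSE
    )
  } else {
    if (is.null(names(species)) || any(!nzchar(names(species)))) {
      stop("species must be named", call. = FALSE)
    }
    sp <- data.frame(
      id = names(species),
      initial_amount = as.numeric(species),
      is_boundary = names(species) %in% boundary,
      stringsAsFactors = FALSE
    )
  }
  if (anyDuplicated(sp$id)) {
    stop(sprintf("duplicate species id '%s'", sp$id[duplicated(sp$id)][1L]),
         call. = FALSE)
  }
  if (any(!is.finite(sp$initial_amount)) || any(sp$initial_amount < 0)) {
    bad <- sp$id[!is.finite(sp$initial_amount) | sp$initial_amount < 0][1L]
    stop(sprintf("species '%s' has negative or non-finite initial amount", bad),
         call. = FALSE)
  }
  if (nrow(sp) < 1L) stop("network needs at least one species", call. = FALSE)

  if (is.null(names(parameters)) || any(!nzchar(names(parameters)))) {
    stop("parameters must be named", call. = FALSE)
  }
  pars <- data.frame(id = names(parameters), value = as.numeric(parameters),
                     stringsAsFactors = FALSE)
  if (anyDuplicated(pars$id)) {
    stop(sprintf("duplicate parameter id '%s'", pars$id[duplicated(pars$id)][1L]),
         call. = FALSE)
  }
  if (any(!is.finite(pars$value)) || any(pars$value <= 0)) {
    bad <- pars$id[!is.finite(pars$value) | pars$value <= 0][1L]
    stop(sprintf("parameter '%s' must be strictly positive", bad), call. = FALSE)
  }
  clash <- intersect(sp$id, pars$id)
  if (length(clash)) {
    stop(sprintf("duplicate id '%s' used for both a species and a parameter",
                 clash[1L]), call. = FALSE)
  }

  if (length(reactions) < 1L) stop("network needs at least one reaction", call. = FALSE)
  allowed <- c(sp$id, pars$id)
  seen_rxn <- character()
  rxns <- lapply(seq_along(reactions), function(i) {
    r <- reactions[[i]]
    id <- if (!is.null(r$id)) as.character(r$id) else sprintf("r%d", i)
    if (id %in% seen_rxn) stop(sprintf("duplicate reaction id '%s'", id), call. = FALSE)
    seen_rxn <<- c(seen_rxn, id)
    st <- r$stoich
    if (is.null(st) || length(st) == 0L || is.null(names(st))) {
      stop(sprintf("reaction '%s': stoichiometry must be a non-empty named vector", id),
           call. = FALSE)
    }
    if (any(!names(st) %in% sp$id)) {
      stop(sprintf("reaction '%s': undeclared species '%s' in stoichiometry",
                   id, setdiff(names(st), sp$id)[1L]), call. = FALSE)
    }
    if (any(st != round(st))) {
      stop(sprintf("reaction '%s': stoichiometry must be integer", id), call. = FALSE)
    }
    rate_str <- as.character(r$rate)
    expr <- parse_rate_expression(rate_str, allowed,
                                  context = sprintf("reaction '%s'", id))
    list(id = id, stoich = st, rate = expr, rate_string = rate_str)
  })

  dyn_ids <- sp$id[!sp$is_boundary]
  if (length(dyn_ids) < 1L) stop("network needs at least one dynamic species", call. = FALSE)

  if (kind == "langevin") {
    if (is.null(diffusion)) {
      stop("langevin networks require an explicit diffusion matrix", call. = FALSE)
    }
    diffusion <- as.matrix(diffusion)
    nd <- length(dyn_ids)
    if (!all(dim(diffusion) == c(nd, nd))) {
      stop("diffusion matrix must be square over the dynamic species", call. = FALSE)
    }
    if (max(abs(diffusion - t(diffusion))) > 1e-12 * max(1, max(abs(diffusion)))) {
      stop("diffusion matrix must be symmetric", call. = FALSE)
    }
    dimnames(diffusion) <- list(dyn_ids, dyn_ids)
  } else if (!is.null(diffusion)) {
    stop("only langevin networks carry an explicit diffusion matrix", call. = FALSE)
  }

  if (is.null(rate_parameters)) {
    rate_parameters <- pars$id
  } else if (any(!rate_parameters %in% pars$id)) {
    stop(sprintf("unknown rate parameter '%s'",
                 setdiff(rate_parameters, pars$id)[1L]), call. = FALSE)
  }

  structure(
    list(species = sp, parameters = pars, reactions = rxns, kind = kind,
         diffusion = diffusion, rate_parameters = rate_parameters, name = name),
    class = "reaction_network"
  )
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network '%s'> (%s)\n", x$name, x$kind))
  cat(sprintf("  species:    %d (%d dynamic, %d boundary)\n",
              nrow(x$species), sum(!x$species$is_boundary), sum(x$species$is_boundary)))
  cat(sprintf("  parameters: %d (%s)\n", nrow(x$parameters),
              paste(x$parameters$id, collapse = ", ")))
  cat(sprintf("  reactions:  %d\n", length(x$reactions)))
  invisible(x)
}

#' Build a network from a structured model description
#'
#' Accepts the native structured-text schema (a file path or a character vector
#' of lines, see [parse_model_text()]) or an already-structured list with
#' fields `species`, `parameters`, `reactions`, and optionally `boundary`,
#' `kind`, `diffusion`, `rate_parameters`, `name`.
#'
#' @param spec model description (path, text lines, or list).
#' @return a validated [reaction_network()].
#' @export
build_network <- function(spec) {
  if (is.character(spec)) {
    spec <- parse_model_text(spec)
  }
  if (inherits(spec, "reaction_network")) return(spec)
  if (!is.list(spec)) stop("spec must be a list, a file path, or schema text", call. = FALSE)
  reaction_network(
    species = spec$species,
    parameters = spec$parameters,
    reactions = spec$reactions,
    kind = if (is.null(spec$kind)) "markov-jump" else spec$kind,
    boundary = if (is.null(spec$boundary)) character() else spec$boundary,
    diffusion = spec$diffusion,
    rate_parameters = spec$rate_parameters,
    name = if (is.null(spec$name)) "network" else spec$name
  )
}

# ---- stoichiometric / conservation analysis --------------------------------

#' Stoichiometric decomposition N = L N_R
#'
#' Computes the full stoichiometry matrix `N` over the dynamic species, a
#' reduced full-row-rank matrix `N_R` over a deterministically chosen set of
#' independent species (greedy scan in declaration order), the link matrix `L`
#' with `N = L N_R`, and the conservation relations (left null space of `N`)
#' with their totals evaluated at the initial amounts.
#'
#' @param net a [reaction_network()].
#' @return an object of class `network_structure` with elements `N`, `N_R`,
#'   `L`, `independent` (ids), `dependent` (ids), `conservation` (matrix of
#'   conserved combinations, rows annihilate `N`) and `totals`.
#' @export
stoichiometric_decomposition <- function(net) {
  stopifnot(inherits(net, "reaction_network"))
  dyn <- net$species[!net$species$is_boundary, , drop = FALSE]
  n_sp <- nrow(dyn)
  n_rx <- length(net$reactions)
  N <- matrix(0, n_sp, n_rx, dimnames = list(dyn$id, vapply(net$reactions, `[[`, "", "id")))
  for (j in seq_len(n_rx)) {
    st <- net$reactions[[j]]$stoich
    keep <- names(st) %in% dyn$id
    if (any(keep)) N[names(st)[keep], j] <- N[names(st)[keep], j] + st[keep]
  }

  # greedy independent-row scan in declaration order
  ind <- integer()
  rk <- 0L
  for (i in seq_len(n_sp)) {
    cand <- N[c(ind, i), , drop = FALSE]
    if (qr(t(cand), tol = 1e-10)$rank > rk) {
      ind <- c(ind, i)
      rk <- rk + 1L
    }
  }
  dep <- setdiff(seq_len(n_sp), ind)

  if (rk == 0L) {
    N_R <- matrix(0, 0L, n_rx, dimnames = list(NULL, colnames(N)))
    L <- matrix(0, n_sp, 0L, dimnames = list(dyn$id, NULL))
  } else {
    N_R <- N[ind, , drop = FALSE]
    # each dynamic-species row is a linear combination of the independent rows
    L <- t(qr.solve(t(N_R), t(N), tol = 1e-12))
    L[abs(L) < 1e-10] <- 0
    L[ind, ] <- diag(1, rk)  # exact identity block for the independent species
    dimnames(L) <- list(dyn$id, dyn$id[ind])
  }

  # conservation: x_d - l_d . x_ind = const for each dependent species
  n_cons <- length(dep)
  conservation <- matrix(0, n_cons, n_sp, dimnames = list(NULL, dyn$id))
  totals <- numeric(n_cons)
  x0 <- stats::setNames(dyn$initial_amount, dyn$id)
  for (k in seq_along(dep)) {
    conservation[k, dep[k]] <- 1
    if (rk > 0L) conservation[k, ind] <- -L[dep[k], ]
    totals[k] <- sum(conservation[k, ] * x0)
  }

  structure(
    list(N = N, N_R = N_R, L = L,
         independent = dyn$id[ind], dependent = dyn$id[dep],
         conservation = conservation, totals = totals,
         species_ids = dyn$id),
    class = "network_structure"
  )
}

#' @export
print.network_structure <- function(x, ...) {
  cat(sprintf("<network_structure> %d species x %d reactions, rank %d\n",
              nrow(x$N), ncol(x$N), nrow(x$N_R)))
  if (length(x$dependent)) {
    cat(sprintf("  conserved: %s\n", paste(x$dependent, collapse = ", ")))
  }
  invisible(x)
}

# ---- rate evaluation and derivatives ---------------------------------------

full_state <- function(net, state) {
  ids <- net$species$id
  if (is.null(names(state))) {
    if (length(state) == length(ids)) {
      state <- stats::setNames(as.numeric(state), ids)
    } else {
      dyn <- ids[!net$species$is_boundary]
      stopifnot(length(state) == length(dyn))
      state <- stats::setNames(as.numeric(state), dyn)
    }
  }
  out <- stats::setNames(net$species$initial_amount, ids)
  out[names(state)] <- state
  out
}

param_values <- function(net, params = NULL) {
  out <- stats::setNames(net$parameters$value, net$parameters$id)
  if (!is.null(params)) {
    if (is.null(names(params)) && length(params) == length(out)) {
      out[] <- as.numeric(params)
    } else {
      out[names(params)] <- params
    }
  }
  out
}

#' Evaluate reaction rates at a state
#'
#' @param net a [reaction_network()].
#' @param state species amounts (named, or in declaration order; boundary
#'   species default to their fixed initial amounts).
#' @param params parameter values (defaults to the model values).
#' @return numeric vector of rates, one per reaction in declaration order.
#' @export
evaluate_rates <- function(net, state, params = NULL) {
  st <- full_state(net, state)
  pv <- param_values(net, params)
  if (any(!is.finite(st))) stop("non-finite state", call. = FALSE)
  if (any(pv <= 0)) stop("parameters must be positive", call. = FALSE)
  env <- rate_eval_env(st, pv)
  v <- vapply(net$reactions, function(r) {
    val <- eval(r$rate, envir = env)
    if (!is.finite(val) || val < 0) {
      stop(sprintf("reaction '%s': rate is negative or non-finite (%g)", r$id, val),
           call. = FALSE)
    }
    val
  }, numeric(1))
  stats::setNames(v, vapply(net$reactions, `[[`, "", "id"))
}

#' Partial derivatives of the reaction rates
#'
#' Returns `dvdx` (reactions x dynamic species) and `dvdp` (reactions x
#' parameters), computed symbolically on the expression grammar or by central
#' finite differences with relative step 1e-6.
#'
#' @inheritParams evaluate_rates
#' @param method `"symbolic"` (default) or `"fd"`.
#' @return list with matrices `dvdx` and `dvdp`.
#' @export
rate_derivatives <- function(net, state, params = NULL,
                             method = c("symbolic", "fd"),
                             what = c("both", "dvdx", "dvdp")) {
  method <- match.arg(method)
  what <- match.arg(what)
  st <- full_state(net, state)
  pv <- param_values(net, params)
  dyn_ids <- net$species$id[!net$species$is_boundary]
  rxn_ids <- vapply(net$reactions, `[[`, "", "id")
  dvdx <- matrix(0, length(rxn_ids), length(dyn_ids),
                 dimnames = list(rxn_ids, dyn_ids))
  dvdp <- matrix(0, length(rxn_ids), nrow(net$parameters),
                 dimnames = list(rxn_ids, net$parameters$id))

  if (method == "symbolic") {
    env <- rate_eval_env(st, pv)
    for (i in seq_along(net$reactions)) {
      r <- net$reactions[[i]]
      vars <- all.vars(r$rate)
      if (what == "dvdp") vars <- setdiff(vars, dyn_ids)
      if (what == "dvdx") vars <- setdiff(vars, colnames(dvdp))
      for (s in intersect(vars, dyn_ids)) {
        d <- eval(deriv_rate_expression(r$rate, s), envir = env)
        if (!is.finite(d)) stop(sprintf("reaction '%s': non-finite derivative", r$id),
                                call. = FALSE)
        dvdx[i, s] <- d
      }
      for (p in intersect(vars, colnames(dvdp))) {
        d <- eval(deriv_rate_expression(r$rate, p), envir = env)
        if (!is.finite(d)) stop(sprintf("reaction '%s': non-finite derivative", r$id),
                                call. = FALSE)
        dvdp[i, p] <- d
      }
    }
  } else {
    rate_at <- function(s, p) {
      env <- rate_eval_env(s, p)
      vapply(net$reactions, function(r) eval(r$rate, envir = env), numeric(1))
    }
    if (what != "dvdp") for (s in dyn_ids) {
      h <- 1e-6 * max(abs(st[[s]]), 1)
      sp <- st; sp[[s]] <- st[[s]] + h
      sm <- st; sm[[s]] <- st[[s]] - h
      dvdx[, s] <- (rate_at(sp, pv) - rate_at(sm, pv)) / (2 * h)
    }
    if (what != "dvdx") for (p in colnames(dvdp)) {
      h <- 1e-6 * abs(pv[[p]])
      pp <- pv; pp[[p]] <- pv[[p]] + h
      pm <- pv; pm[[p]] <- pv[[p]] - h
      dvdp[, p] <- (rate_at(st, pp) - rate_at(st, pm)) / (2 * h)
    }
    if (any(!is.finite(dvdx)) || any(!is.finite(dvdp))) {
      stop("non-finite finite-difference rate derivative", call. = FALSE)
    }
  }
  list(dvdx = dvdx, dvdp = dvdp)
}
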