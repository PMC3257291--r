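# Native structured-text model schema.
#
#   name: birth_death
#   kind: markov-jump
#   species:
#     X = 5
#     E = 10 boundary
#   parameters:
#     k_s = 2
#     k_d = 0.4
#   reactions:
#     synthesis: 0 -> X ; rate: k_s
#     degradation: X -> 0 ; rate: k_d * X
#   diffusion:           # langevin networks only, one row per dynamic species
#     0.1 0
#     0 0.2
#   rate_parameters: k_s k_d
#
# Reaction sides are integer-weighted sums of species ids ('2 A + B'); '0'
# denotes an empty side. The stored stoichiometry is the net change
# (products minus reactants). Lines starting with '#' are comments.

#' Parse the native model schema
#'
#' @param text a file path or a character vector of schema lines.
#' @return a list suitable for [build_network()].
#' @export
parse_model_text <- function(text) {
  if (length(text) == 1L && file.exists(text)) {
    text <- readLines(text, warn = FALSE)
  }
  lines <- sub("^\\s*#.*$", "", text)
  spec <- list(species = numeric(), boundary = character(),
               parameters = numeric(), reactions = list(),
               diffusion_rows = list())
  section <- NULL
  for (ln in lines) {
    s <- trimws(ln)
    if (!nzchar(s)) next
    if (grepl("^(species|parameters|reactions|diffusion):\\s*$", s)) {
      section <- sub(":\\s*$", "", s)
      next
    }
    if (grepl("^name:", s)) { spec$name <- trimws(sub("^name:", "", s)); section <- NULL; next }
    if (grepl("^kind:", s)) { spec$kind <- trimws(sub("^kind:", "", s)); section <- NULL; next }
    if (grepl("^rate_parameters:", s)) {
      spec$rate_parameters <- strsplit(trimws(sub("^rate_parameters:", "", s)), "\\s+")[[1]]
      section <- NULL
      next
    }
    if (is.null(section)) {
      stop(sprintf("schema error: line '%s' outside any section", s), call. = FALSE)
    }
    if (section == "species") {
      m <- regmatches(s, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*([-0-9.eE+]+)\\s*(boundary)?$", s))[[1]]
      if (length(m) == 0L) stop(sprintf("schema error in species line '%s'", s), call. = FALSE)
      spec$species[m[2]] <- as.numeric(m[3])
      if (nzchar(m[4])) spec$boundary <- c(spec$boundary, m[2])
    } else if (section == "parameters") {
      m <- regmatches(s, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*([-0-9.eE+]+)$", s))[[1]]
      if (length(m) == 0L) stop(sprintf("schema error in parameter line '%s'", s), call. = FALSE)
      spec$parameters[m[2]] <- as.numeric(m[3])
    } else if (section == "reactions") {
      m <- regmatches(s, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.*?)\\s*->\\s*(.*?)\\s*;\\s*rate:\\s*(.*)$", s))[[1]]
      if (length(m) == 0L) stop(sprintf("schema error in reaction line '%s'", s), call. = FALSE)
      lhs <- parse_reaction_side(m[3])  # reactants
      rhs <- parse_reaction_side(m[4])  # products
      st <- rhs
      for (id in names(lhs)) st[id] <- (if (id %in% names(st)) st[id] else 0) - lhs[id]
      st <- st[st != 0]
      if (length(st) == 0L) {
        stop(sprintf("schema error: reaction '%s' has zero net stoichiometry", m[2]),
             call. = FALSE)
      }
      spec$reactions[[length(spec$reactions) + 1L]] <-
        list(id = m[2], stoich = st, rate = m[5])
    } else if (section == "diffusion") {
      spec$diffusion_rows[[length(spec$diffusion_rows) + 1L]] <-
        as.numeric(strsplit(s, "\\s+")[[1]])
    }
  }
  if (length(spec$diffusion_rows)) {
    spec$diffusion <- do.call(rbind, spec$diffusion_rows)
  }
  spec$diffusion_rows <- NULL
  if (length(spec$rate_parameters) == 0L) spec$rate_parameters <- NULL
  spec
}

parse_reaction_side <- function(side) {
  side <- trimws(side)
  if (side == "0" || side == "") return(stats::setNames(numeric(0), character(0)))
  terms <- strsplit(side, "\\+")[[1]]
  out <- numeric(0)
  for (tm in terms) {
    tm <- trimws(tm)
    m <- regmatches(tm, regexec("^([0-9]+)?\\s*([A-Za-z_][A-Za-z0-9_]*)$", tm))[[1]]
    if (length(m) == 0L) stop(sprintf("schema error in reaction side term '%s'", tm),
                              call. = FALSE)
    coef <- if (nzchar(m[2])) as.numeric(m[2]) else 1
    out[m[3]] <- (if (m[3] %in% names(out)) out[m[3]] else 0) + coef
  }
  out
}

#' Serialize a network to the native model schema
#'
#' The written text round-trips through [build_network()] to a network with
#' identical stoichiometry, rate laws and values.
#'
#' @param net a [reaction_network()].
#' @param path optional file path; when given, lines are written there.
#' @return the schema lines, invisibly when `path` is given.
#' @export
write_model_text <- function(net, path = NULL) {
  stopifnot(inherits(net, "reaction_network"))
  fmt <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  lines <- c(sprintf("name: %s", net$name), sprintf("kind: %s", net$kind), "species:")
  for (i in seq_len(nrow(net$species))) {
    lines <- c(lines, sprintf("  %s = %s%s", net$species$id[i],
                              fmt(net$species$initial_amount[i]),
                              if (net$species$is_boundary[i]) " boundary" else ""))
  }
  lines <- c(lines, "parameters:")
  for (i in seq_len(nrow(net$parameters))) {
    lines <- c(lines, sprintf("  %s = %s", net$parameters$id[i],
                              fmt(net$parameters$value[i])))
  }
  lines <- c(lines, "reactions:")
  side_str <- function(st) {
    if (length(st) == 0L) return("0")
    paste(vapply(seq_along(st), function(i) {
      if (st[i] == 1) names(st)[i] else sprintf("%d %s", as.integer(st[i]), names(st)[i])
    }, ""), collapse = " + ")
  }
  for (r in net$reactions) {
    st <- r$stoich[r$stoich != 0]
    lhs <- -st[st < 0]
    rhs <- st[st > 0]
    lines <- c(lines, sprintf("  %s: %s -> %s ; rate: %s", r$id,
                              side_str(lhs), side_str(rhs), r$rate_string))
  }
  if (!is.null(net$diffusion)) {
    lines <- c(lines, "diffusion:",
               apply(net$diffusion, 1, function(row) paste0("  ", paste(fmt(row), collapse = " "))))
  }
  if (!identical(net$rate_parameters, net$parameters$id)) {
    lines <- c(lines, sprintf("rate_parameters: %s",
                              paste(net$rate_parameters, collapse = " ")))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
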