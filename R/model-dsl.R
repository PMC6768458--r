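#' Parse a textual reaction rule set into a reaction model
#'
#' Rules are written one per line (or separated by `;`) in the form
#' `LHS -> RHS : rate`.  Each side is a `+`-separated list of terms, where a
#' term is `name`, `2 name` (an integer stoichiometric coefficient), or
#' `(name)` for a constant reservoir species whose abundance is not part of
#' the dynamic state.  `EMPTY` denotes the empty side.  Rates are arithmetic
#' expressions over parameters only; every free symbol in a rate becomes a
#' model parameter.  Blank lines and `#` comments are ignored.
#'
#' The symbols `V` (system size), `t` (time), and names beginning with `Phi`
#' or `eta` (population proportions and fluctuation variables used by the
#' derived representations) are reserved and rejected as species or parameter
#' names.
#'
#' @param text a string containing the rule set.
#' @return an object of class `reaction_model` with components `species`
#'   (a tibble with columns `name`, `constant`), `reactions`, `parameters`,
#'   `eliminated` (species removed by [substitute_model()]) and
#'   `conserved_total`.
#' @examples
#' m <- parse_model("(A) -> X : k
#'                   X + X -> EMPTY : h")
#' m
#' stoichiometry(m)
#' @seealso [substitute_model()], [stoichiometry()], [derive_odes()]
#' @export
parse_model <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  rules <- list()
  for (ln in seq_along(lines)) {
    raw <- sub("#.*$", "", lines[[ln]])
    for (piece in unlist(strsplit(raw, ";", fixed = TRUE))) {
      piece <- trimws(piece)
      if (nzchar(piece)) rules[[length(rules) + 1L]] <- list(text = piece, line = ln)
    }
  }
  if (length(rules) == 0L) stop("no rules found in model text", call. = FALSE)

  species <- character(0)
  constant <- logical(0)
  note_species <- function(name, is_const) {
    if (!(name %in% species)) {
      species <<- c(species, name)
      constant <<- c(constant, is_const)
    } else if (constant[match(name, species)] != is_const) {
      stop("species '", name, "' used both as constant and dynamic", call. = FALSE)
    }
  }

  parse_side <- function(side, line) {
    side <- trimws(side)
    if (side == "EMPTY") return(list())
    if (grepl("^\\+|\\+\\s*$|\\+\\s*\\+", side)) {
      stop("line ", line, ": dangling '+' in '", side, "'", call. = FALSE)
    }
    terms <- trimws(unlist(strsplit(side, "+", fixed = TRUE)))
    out <- list()
    for (tm in terms) {
      if (grepl("^\\(\\s*[A-Za-z_][A-Za-z0-9_]*\\s*\\)$", tm)) {
        nm <- trimws(sub("^\\((.*)\\)$", "\\1", tm))
        check_symbol_name(nm, "species", line)
        note_species(nm, TRUE)
        out[[length(out) + 1L]] <- list(name = nm, coef = 1L)
      } else if (grepl("^([0-9]+\\s*)?[A-Za-z_][A-Za-z0-9_]*$", tm)) {
        co <- sub("^([0-9]*).*$", "\\1", tm)
        nm <- trimws(sub("^[0-9]*\\s*", "", tm))
        co <- if (nzchar(co)) as.integer(co) else 1L
        if (co < 1L) {
          stop("line ", line, ": stoichiometric coefficient must be >= 1 in term '",
               tm, "'", call. = FALSE)
        }
        check_symbol_name(nm, "species", line)
        note_species(nm, FALSE)
        out[[length(out) + 1L]] <- list(name = nm, coef = co)
      } else {
        stop("line ", line, ": cannot parse term '", tm, "'", call. = FALSE)
      }
    }
    out
  }

  reactions <- list()
  seen_rules <- character(0)
  for (r in rules) {
    m <- regmatches(r$text, regexec("^(.*?)->(.*?):(.*)$", r$text))[[1]]
    if (length(m) != 4L) {
      stop("line ", r$line, ": rule does not match 'LHS -> RHS : rate': '",
           r$text, "'", call. = FALSE)
    }
    lhs <- parse_side(m[[2]], r$line)
    rhs <- parse_side(m[[3]], r$line)
    if (length(lhs) == 0L && length(rhs) == 0L) {
      stop("line ", r$line, ": both sides of the rule are EMPTY", call. = FALSE)
    }
    rate_text <- trimws(m[[4]])
    if (!nzchar(rate_text)) stop("line ", r$line, ": missing rate", call. = FALSE)
    rate_lang <- tryCatch(str2lang(rate_text), error = function(e) {
      stop("line ", r$line, ": cannot parse rate expression '", rate_text, "'",
           call. = FALSE)
    })
    rate <- q_from_lang(rate_lang)
    key <- paste(side_text(lhs, list()), "->", side_text(rhs, list()),
                 ":", q_deparse(rate))
    if (key %in% seen_rules) {
      warning("duplicate rule kept as separate reaction: '", r$text, "'",
              call. = FALSE)
    }
    seen_rules <- c(seen_rules, key)
    reactions[[length(reactions) + 1L]] <- list(
      lhs = lhs, rhs = rhs,
      reactants = side_multiset(lhs), products = side_multiset(rhs),
      rate = rate, rate_lang = rate_lang
    )
  }

  params <- character(0)
  for (rx in reactions) {
    for (s in q_vars(rx$rate)) {
      if (s %in% species) {
        stop("rate expression uses species symbol '", s,
             "'; rates must be expressions over parameters only", call. = FALSE)
      }
      check_symbol_name(s, "parameter")
      params <- union(params, s)
    }
  }

  structure(list(
    species = tibble::tibble(name = species, constant = constant),
    reactions = reactions,
    parameters = params,
    eliminated = list(),
    conserved_total = character(0)
  ), class = "reaction_model")
}

check_symbol_name <- function(name, what, line = NULL) {
  reserved <- name %in% c("V", "t", "EMPTY", "Phi", "eta") ||
    grepl("^Phi_", name) || grepl("^eta_", name)
  if (reserved) {
    where <- if (is.null(line)) "" else paste0("line ", line, ": ")
    stop(where, "'", name, "' is a reserved symbol and cannot be used as a ",
         what, " name", call. = FALSE)
  }
  invisible(name)
}

side_multiset <- function(terms) {
  out <- integer(0)
  for (tm in terms) {
    cur <- if (tm$name %in% names(out)) out[[tm$name]] else 0L
    out[[tm$name]] <- cur + tm$coef
  }
  out
}

side_text <- function(terms, const_flags) {
  if (length(terms) == 0L) return("EMPTY")
  paste(vapply(terms, function(tm) {
    is_const <- tm$name %in% names(const_flags) && isTRUE(const_flags[[tm$name]])
    nm <- if (is_const) paste0("(", tm$name, ")") else tm$name
    if (tm$coef == 1L) nm else paste(tm$coef, nm)
  }, character(1)), collapse = " + ")
}

#' Dynamic species of a model
#'
#' Species that are neither constant reservoirs nor eliminated via
#' [substitute_model()]; these span the dynamic state.
#' @param model a `reaction_model`.
#' @return character vector of species names, in declaration order.
#' @export
dynamic_species <- function(model) {
  stopifnot(inherits(model, "reaction_model"))
  setdiff(model$species$name[!model$species$constant], names(model$eliminated))
}

constant_species <- function(model) model$species$name[model$species$constant]

#' Net stoichiometry matrix
#'
#' Column j holds the net change (products minus reactants) of each dynamic
#' species when reaction j fires once.  Constant and eliminated species are
#' excluded.
#' @param model a `reaction_model`.
#' @return integer matrix, dynamic species x reactions.
#' @export
stoichiometry <- function(model) {
  stopifnot(inherits(model, "reaction_model"))
  dyn <- dynamic_species(model)
  S <- matrix(0L, nrow = length(dyn), ncol = length(model$reactions),
              dimnames = list(dyn, NULL))
  for (j in seq_along(model$reactions)) {
    rx <- model$reactions[[j]]
    for (nm in names(rx$products)) {
      if (nm %in% dyn) S[nm, j] <- S[nm, j] + rx$products[[nm]]
    }
    for (nm in names(rx$reactants)) {
      if (nm %in% dyn) S[nm, j] <- S[nm, j] - rx$reactants[[nm]]
    }
  }
  S
}

#' Eliminate species or rewrite parameters by substitution
#'
#' Accepts substitution specifications of the form `"target = expression"`,
#' either as a comma-separated string (as in `"a_A = 1/v_A, a_B = 1/v_B"`) or
#' a character vector.  A species target is eliminated from the dynamic state:
#' all derived expressions (drifts, propensities, master-equation factors)
#' replace its abundance by the given expression, and the dimension of the
#' derived ODE system drops by one.  A parameter target is rewritten inside
#' every rate.  When a species is replaced by `total - sum(other species)`
#' with a fresh symbol for the total, that symbol is recorded as the model's
#' conserved total.  The input model is not modified.
#'
#' @param model a `reaction_model`.
#' @param specs substitution specification(s), e.g. `"U = N - A - B"`.
#' @return a new `reaction_model`.
#' @examples
#' bees <- load_fixture("honeybee")$model
#' reduced <- substitute_model(bees, "U = N - A - B")
#' dynamic_species(reduced)
#' @export
substitute_model <- function(model, specs) {
  stopifnot(inherits(model, "reaction_model"), is.character(specs))
  specs <- trimws(unlist(strsplit(specs, ",", fixed = TRUE)))
  specs <- specs[nzchar(specs)]
  out <- model
  for (sp in specs) {
    eq <- regmatches(sp, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.+)$", sp))[[1]]
    if (length(eq) != 3L) stop("cannot parse substitution '", sp, "'", call. = FALSE)
    target <- eq[[2]]
    rep_lang <- str2lang(eq[[3]])
    repq <- q_from_lang(rep_lang)
    out <- apply_one_substitution(out, target, repq)
  }
  out
}

apply_one_substitution <- function(model, target, repq) {
  all_species <- model$species$name
  new_syms <- setdiff(q_vars(repq), c(all_species, model$parameters))
  for (s in new_syms) check_symbol_name(s, "parameter")

  if (target %in% all_species) {
    if (model$species$constant[match(target, all_species)]) {
      stop("cannot eliminate constant species '", target, "'", call. = FALSE)
    }
    if (target %in% names(model$eliminated)) {
      stop("species '", target, "' already eliminated", call. = FALSE)
    }
    # propagate into previously recorded eliminations
    model$eliminated <- lapply(model$eliminated, q_subst_sym, sym = target, rep = repq)
    model$eliminated[[target]] <- repq
    model$parameters <- union(model$parameters, new_syms)
    # conserved total: replacement == total - (sum of the other dynamic species)
    if (length(new_syms) == 1L) {
      others <- setdiff(all_species[!model$species$constant],
                        c(target, names(model$eliminated)))
      expect <- q_sym(new_syms)
      for (o in others) expect <- q_sub(expect, q_sym(o))
      if (q_equal(repq, expect)) {
        model$conserved_total <- union(model$conserved_total, new_syms)
      }
    }
  } else if (target %in% model$parameters) {
    clash <- intersect(q_vars(repq), model$species$name)
    if (length(clash) > 0L) {
      stop("replacement for parameter '", target,
           "' introduces species symbol(s) into rates: ",
           paste(clash, collapse = ", "), call. = FALSE)
    }
    model$reactions <- lapply(model$reactions, function(rx) {
      rx$rate <- q_subst_sym(rx$rate, target, repq)
      rx$rate_lang <- q_to_lang(rx$rate)
      rx
    })
    model$eliminated <- lapply(model$eliminated, q_subst_sym, sym = target, rep = repq)
  } else {
    stop("substitution target '", target,
         "' is neither a species nor a parameter of the model", call. = FALSE)
  }
  # the parameter set is whatever free symbols the rates and the elimination
  # expressions now use, minus species symbols
  used <- unique(unlist(c(lapply(model$reactions, function(rx) q_vars(rx$rate)),
                          lapply(model$eliminated, q_vars))))
  model$parameters <- setdiff(used, model$species$name)
  model
}

#' Canonical rule text of a model
#'
#' Serializes the underlying rule set to the same plain-text grammar accepted
#' by [parse_model()]; re-parsing yields a symbolically identical model.
#' Species eliminations are derived-state operations and are not part of the
#' rule text.
#' @param model a `reaction_model`.
#' @return a single string.
#' @export
model_text <- function(model) {
  stopifnot(inherits(model, "reaction_model"))
  const <- stats::setNames(as.list(model$species$constant), model$species$name)
  paste(vapply(model$reactions, function(rx) {
    paste(side_text(rx$lhs, const), "->", side_text(rx$rhs, const), ":",
          q_deparse(rx$rate))
  }, character(1)), collapse = "\n")
}

#' Read or write a model file
#'
#' Plain UTF-8 `.rxn` files in the [parse_model()] grammar.
#' @param path file path.
#' @return `read_model()` returns a `reaction_model`; `write_model()` returns
#'   `path` invisibly.
#' @export
read_model <- function(path) {
  parse_model(paste(readLines(path, encoding = "UTF-8"), collapse = "\n"))
}

#' @rdname read_model
#' @param model a `reaction_model`.
#' @export
write_model <- function(model, path) {
  writeLines(model_text(model), path, useBytes = FALSE)
  invisible(path)
}

#' @export
print.reaction_model <- function(x, ...) {
  dyn <- dynamic_species(x)
  cat("<reaction_model> ", length(x$reactions), " reaction(s)\n", sep = "")
  cat(model_text(x), "\n")
  cat("dynamic species:", paste(dyn, collapse = ", "), "\n")
  if (any(x$species$constant)) {
    cat("constant species:", paste(constant_species(x), collapse = ", "), "\n")
  }
  if (length(x$eliminated) > 0L) {
    for (nm in names(x$eliminated)) {
      cat("eliminated:", nm, "=", q_deparse(x$eliminated[[nm]]), "\n")
    }
  }
  cat("parameters:", paste(sort(x$parameters), collapse = ", "), "\n")
  invisible(x)
}
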