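# Exact rational-polynomial engine.
#
# Every symbolic quantity the package derives (mass-action drifts, Jacobians,
# master-equation propensity factors, van Kampen expansion coefficients) is a
# ratio of multivariate Laurent polynomials with numeric coefficients.  A
# polynomial is a named numeric vector: names are canonical monomial keys
# ("" for the constant term, otherwise "sym^pow" pieces sorted by symbol and
# joined by "*"; powers are integers and may be negative, which is used only
# for the internal square-root-of-system-size symbol).  A rational is a
# list(num, den) of two such polynomials, class "rxq".
#
# Coefficients are doubles; cancellation residues are cleaned relative to the
# largest coefficient of the polynomial, so identities built from exact or
# dyadic inputs test as exact.

.RX_TOL <- 1e-10

mono_parse <- function(key) {
  if (key == "") return(stats::setNames(integer(0), character(0)))
  parts <- strsplit(key, "*", fixed = TRUE)[[1]]
  sp <- strsplit(parts, "^", fixed = TRUE)
  pw <- vapply(sp, function(x) as.integer(x[[2]]), integer(1))
  names(pw) <- vapply(sp, `[[`, character(1), 1)
  pw
}

mono_key <- function(ex) {
  ex <- ex[ex != 0L]
  if (length(ex) == 0L) return("")
  ex <- ex[order(names(ex))]
  paste(paste0(names(ex), "^", ex), collapse = "*")
}

mono_mul <- function(k1, k2) {
  if (k1 == "") return(k2)
  if (k2 == "") return(k1)
  e1 <- mono_parse(k1); e2 <- mono_parse(k2)
  all <- union(names(e1), names(e2))
  ex <- stats::setNames(integer(length(all)), all)
  ex[names(e1)] <- e1
  ex[names(e2)] <- ex[names(e2)] + e2
  mono_key(ex)
}

p_clean <- function(p) {
  if (length(p) == 0L) return(p)
  scale <- max(abs(p), 1)
  p <- p[abs(p) > .RX_TOL * scale]
  p
}

p_zero <- function() stats::setNames(numeric(0), character(0))

p_const <- function(x) {
  if (x == 0) return(p_zero())
  stats::setNames(as.numeric(x), "")
}

p_sym <- function(name, pow = 1L) {
  stats::setNames(1, mono_key(stats::setNames(as.integer(pow), name)))
}

p_add <- function(a, b) {
  v <- c(a, b)
  if (length(v) == 0L) return(p_zero())
  s <- vapply(split(unname(v), names(v)), sum, numeric(1))
  p_clean(s)
}

p_neg <- function(a) -a

p_scale <- function(a, k) {
  if (k == 0) return(p_zero())
  p_clean(a * k)
}

p_mul <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) return(p_zero())
  keys <- character(0); vals <- numeric(0)
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      keys <- c(keys, mono_mul(names(a)[i], names(b)[j]))
      vals <- c(vals, unname(a[i]) * unname(b[j]))
    }
  }
  names(vals) <- keys
  p_add(vals, p_zero())
}

p_pow <- function(a, n) {
  n <- as.integer(n)
  stopifnot(n >= 0L)
  out <- p_const(1)
  for (i in seq_len(n)) out <- p_mul(out, a)
  out
}

p_vars <- function(a) {
  if (length(a) == 0L) return(character(0))
  unique(unlist(lapply(names(a), function(k) names(mono_parse(k)))))
}

p_diff <- function(a, sym) {
  out <- p_zero()
  for (i in seq_along(a)) {
    ex <- mono_parse(names(a)[i])
    e <- ex[sym]
    if (!is.na(e) && e != 0L) {
      ex[sym] <- e - 1L
      out <- p_add(out, stats::setNames(unname(a[i]) * e, mono_key(ex)))
    }
  }
  out
}

p_eval <- function(a, env) {
  if (length(a) == 0L) return(0)
  tot <- 0
  for (i in seq_along(a)) {
    ex <- mono_parse(names(a)[i])
    miss <- setdiff(names(ex), names(env))
    if (length(miss) > 0L) {
      stop("unbound symbol(s) in expression: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    tot <- tot + unname(a[i]) * prod(unlist(env[names(ex)])^ex)
  }
  tot
}

# substitute numeric values for a subset of symbols
p_bind <- function(a, env) {
  out <- p_zero()
  for (i in seq_along(a)) {
    ex <- mono_parse(names(a)[i])
    hit <- names(ex) %in% names(env)
    val <- unname(a[i]) * prod(unlist(env[names(ex)[hit]])^ex[hit])
    out <- p_add(out, stats::setNames(val, mono_key(ex[!hit])))
  }
  out
}

# coefficient polynomial of sym^pow (sym removed); pow may be 0
p_component <- function(a, sym, pow) {
  out <- p_zero()
  for (i in seq_along(a)) {
    ex <- mono_parse(names(a)[i])
    e <- if (sym %in% names(ex)) ex[[sym]] else 0L
    if (e == pow) {
      ex <- ex[names(ex) != sym]
      out <- p_add(out, stats::setNames(unname(a[i]), mono_key(ex)))
    }
  }
  out
}

p_degree <- function(a, sym) {
  if (length(a) == 0L) return(-Inf)
  max(vapply(names(a), function(k) {
    ex <- mono_parse(k)
    if (sym %in% names(ex)) ex[[sym]] else 0L
  }, integer(1)))
}

# dense univariate coefficient vector c0, c1, ..., cd; errors on foreign symbols
p_unicoeffs <- function(a, var) {
  vs <- p_vars(a)
  if (!all(vs %in% var)) {
    stop("polynomial is not univariate in ", var, ": contains ",
         paste(setdiff(vs, var), collapse = ", "), call. = FALSE)
  }
  d <- max(0L, p_degree(a, var))
  co <- numeric(d + 1L)
  for (i in seq_along(a)) {
    ex <- mono_parse(names(a)[i])
    e <- if (var %in% names(ex)) ex[[var]] else 0L
    if (e < 0L) stop("negative power of ", var, call. = FALSE)
    co[e + 1L] <- co[e + 1L] + unname(a[i])
  }
  co
}

## ---- rationals -------------------------------------------------------------

q_new <- function(num, den = p_const(1)) {
  if (length(den) == 0L) stop("division by zero in symbolic expression", call. = FALSE)
  # normalise so the lexicographically first denominator coefficient is 1
  lead <- unname(den[order(names(den))][1])
  structure(list(num = p_clean(num / lead), den = p_clean(den / lead)),
            class = "rxq")
}

q_const <- function(x) q_new(p_const(x))
q_sym <- function(name) q_new(p_sym(name))

q_is_const <- function(q) length(p_vars(q$num)) == 0L && length(p_vars(q$den)) == 0L

q_den_is_one <- function(q) identical(names(q$den), "") && abs(unname(q$den[1]) - 1) < .RX_TOL

q_add <- function(a, b) {
  if (identical(names(a$den), names(b$den)) &&
      isTRUE(all(abs(a$den - b$den[names(a$den)]) < .RX_TOL * max(abs(a$den), 1)))) {
    return(q_new(p_add(a$num, b$num), a$den))
  }
  q_new(p_add(p_mul(a$num, b$den), p_mul(b$num, a$den)), p_mul(a$den, b$den))
}

q_neg <- function(a) q_new(p_neg(a$num), a$den)
q_sub <- function(a, b) q_add(a, q_neg(b))
q_mul <- function(a, b) q_new(p_mul(a$num, b$num), p_mul(a$den, b$den))

q_div <- function(a, b) {
  if (length(b$num) == 0L) stop("division by zero in symbolic expression", call. = FALSE)
  q_new(p_mul(a$num, b$den), p_mul(a$den, b$num))
}

q_pow <- function(a, n) {
  n <- as.integer(n)
  if (n < 0L) return(q_pow(q_div(q_const(1), a), -n))
  q_new(p_pow(a$num, n), p_pow(a$den, n))
}

q_diff <- function(a, sym) {
  if (q_den_is_one(a)) return(q_new(p_diff(a$num, sym)))
  q_new(p_add(p_mul(p_diff(a$num, sym), a$den),
              p_neg(p_mul(a$num, p_diff(a$den, sym)))),
        p_mul(a$den, a$den))
}

q_vars <- function(a) union(p_vars(a$num), p_vars(a$den))

q_eval <- function(a, env) p_eval(a$num, env) / p_eval(a$den, env)

q_bind <- function(a, env) q_new(p_bind(a$num, env), p_bind(a$den, env))

q_subst_sym <- function(a, sym, rep) {
  sub_poly <- function(p) {
    out <- q_const(0)
    for (i in seq_along(p)) {
      ex <- mono_parse(names(p)[i])
      e <- if (sym %in% names(ex)) ex[[sym]] else 0L
      rest <- q_new(stats::setNames(unname(p[i]), mono_key(ex[names(ex) != sym])))
      out <- q_add(out, if (e == 0L) rest else q_mul(rest, q_pow(rep, e)))
    }
    out
  }
  q_div(sub_poly(a$num), sub_poly(a$den))
}

q_is_zero <- function(a) length(p_clean(a$num)) == 0L

q_equal <- function(a, b) {
  n1d2 <- p_mul(a$num, b$den)
  n2d1 <- p_mul(b$num, a$den)
  d <- p_add(n1d2, p_neg(n2d1))
  if (length(d) == 0L) return(TRUE)
  ref <- max(abs(c(n1d2, n2d1, 1)))
  all(abs(d) <= 1e-8 * ref)
}

## ---- R language <-> rational ----------------------------------------------

q_from_lang <- function(x) {
  if (is.numeric(x)) return(q_const(x))
  if (is.name(x)) return(q_sym(as.character(x)))
  if (is.call(x)) {
    op <- as.character(x[[1]])
    if (op == "(") return(q_from_lang(x[[2]]))
    if (op == "+" && length(x) == 2L) return(q_from_lang(x[[2]]))
    if (op == "-" && length(x) == 2L) return(q_neg(q_from_lang(x[[2]])))
    if (length(x) == 3L) {
      a <- q_from_lang(x[[2]])
      if (op == "^") {
        n <- tryCatch(eval(x[[3]], baseenv()), error = function(e) NULL)
        if (is.null(n) || !is.numeric(n) || n != round(n)) {
          stop("exponent must be an integer constant in: ", deparse(x), call. = FALSE)
        }
        return(q_pow(a, n))
      }
      b <- q_from_lang(x[[3]])
      return(switch(op,
        "+" = q_add(a, b),
        "-" = q_sub(a, b),
        "*" = q_mul(a, b),
        "/" = q_div(a, b),
        stop("unsupported operator '", op, "' in rate expression: ",
             deparse(x), call. = FALSE)
      ))
    }
  }
  stop("cannot interpret symbolic expression: ", deparse(x), call. = FALSE)
}

q_parse <- function(text) q_from_lang(str2lang(text))

poly_to_lang <- function(p) {
  if (length(p) == 0L) return(0)
  ks <- order(names(p))
  terms <- vector("list", length(p))
  for (i in seq_along(ks)) {
    idx <- ks[i]
    ex <- mono_parse(names(p)[idx])
    co <- unname(p[idx])
    piece <- NULL
    for (s in names(ex)) {
      f <- if (ex[[s]] == 1L) as.name(s) else call("^", as.name(s), as.numeric(ex[[s]]))
      piece <- if (is.null(piece)) f else call("*", piece, f)
    }
    if (is.null(piece)) {
      piece <- co
    } else if (abs(co - 1) > .RX_TOL) {
      piece <- if (abs(co + 1) < .RX_TOL) call("-", piece) else call("*", co, piece)
    }
    terms[[i]] <- piece
  }
  Reduce(function(a, b) call("+", a, b), terms)
}

q_to_lang <- function(q) {
  if (q_den_is_one(q)) return(poly_to_lang(q$num))
  den <- poly_to_lang(q$den)
  if (length(q$den) > 1L) den <- call("(", den)
  call("/", poly_to_lang(q$num), den)
}

q_deparse <- function(q) {
  x <- q_to_lang(q)
  paste(deparse(x, width.cutoff = 500L), collapse = " ")
}

#' @export
print.rxq <- function(x, ...) {
  cat(q_deparse(x), "\n")
  invisible(x)
}
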