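#' Default BNF grammar for feature expressions
#'
#' An ordered context-free grammar over arithmetic expressions of the
#' original features `x1..xd`:
#'
#' ```
#' <expr>     ::= ( <expr> <op> <expr> )   (0)
#'              | <func> ( <expr> )        (1)
#'              | <terminal>               (2)
#' <op>       ::= + | - | * | /
#' <func>     ::= sin | cos | exp | log
#' <terminal> ::= <xlist> | <const>
#' <xlist>    ::= x1 | x2 | ... | xd
#' <const>    ::= <digit> . <digit>
#' <digit>    ::= 0 | 1 | ... | 9
#' ```
#'
#' Rule order matters: codon-to-rule mapping selects rule
#' `codon mod NR` among the ordered alternatives of the nonterminal
#' under expansion. Numeric constants (a one-digit integer part and one
#' fractional digit) can be disabled with `use_constants = FALSE`, in
#' which case `<terminal>` has the single `<xlist>` alternative.
#'
#' @param d Number of input features (dimension of the data).
#' @param use_constants Include the decimal-constant terminal branch
#'   (default TRUE).
#' @return An object of class `bnf_grammar` with fields `start`,
#'   `productions` (named list of rule lists, each rule a character
#'   vector of symbols), and `d`.
#' @export
default_feature_grammar <- function(d, use_constants = TRUE) {
  d <- as.integer(d)
  if (d < 1L) stop("d must be >= 1")
  terminal_rules <- if (use_constants) {
    list("<xlist>", "<const>")
  } else {
    list("<xlist>")
  }
  productions <- list(
    "<expr>" = list(c("(", "<expr>", "<op>", "<expr>", ")"),
                    c("<func>", "(", "<expr>", ")"),
                    c("<terminal>")),
    "<op>" = list("+", "-", "*", "/"),
    "<func>" = list("sin", "cos", "exp", "log"),
    "<terminal>" = terminal_rules,
    "<xlist>" = as.list(paste0("x", seq_len(d))),
    "<const>" = list(c("<digit>", ".", "<digit>")),
    "<digit>" = as.list(as.character(0:9))
  )
  if (!use_constants) productions[["<const>"]] <- NULL
  structure(list(start = "<expr>", productions = productions, d = d),
            class = "bnf_grammar")
}

is_nonterminal <- function(sym, grammar) sym %in% names(grammar$productions)

#' Number of production rules for a nonterminal
#'
#' @param grammar A `bnf_grammar`.
#' @param nt Nonterminal symbol, e.g. `"<expr>"`.
#' @return Integer rule count.
#' @export
n_rules <- function(grammar, nt) {
  rules <- grammar$productions[[nt]]
  if (is.null(rules)) stop("unknown nonterminal: ", nt)
  length(rules)
}

#' Serialize a grammar as plain-text BNF
#'
#' @param grammar A `bnf_grammar`.
#' @return Character vector, one production per line, alternatives
#'   separated by `|` in rule order.
#' @export
format_grammar <- function(grammar) {
  vapply(names(grammar$productions), function(nt) {
    alts <- vapply(grammar$productions[[nt]], paste, collapse = " ",
                   FUN.VALUE = character(1))
    sprintf("%s ::= %s", nt, paste(alts, collapse = " | "))
  }, character(1))
}

#' @export
print.bnf_grammar <- function(x, ...) {
  cat(format_grammar(x), sep = "\n")
  invisible(x)
}

#' Integer chromosome
#'
#' @param codons Integer vector, each in `[0, bounds]`.
#' @param bounds Maximum codon value (default 255).
#' @return An object of class `ge_chromosome`.
#' @export
chromosome <- function(codons, bounds = 255L) {
  codons <- as.integer(codons)
  if (any(codons < 0L) || any(codons > bounds)) {
    stop("codons must lie in [0, ", bounds, "]")
  }
  structure(list(codons = codons, bounds = as.integer(bounds)),
            class = "ge_chromosome")
}

#' Map a chromosome to an expression via codon-to-rule derivation
#'
#' Performs the leftmost derivation from the grammar's start symbol: at
#' each nonterminal the next codon `V` selects rule `V mod NR` among
#' the `NR` ordered alternatives. When the codon stream is exhausted it
#' wraps to the start, up to `max_wraps` times; a derivation still
#' incomplete after the wrap budget is marked invalid.
#'
#' @param chrom A [chromosome()] or integer vector.
#' @param grammar A `bnf_grammar` from [default_feature_grammar()].
#' @param max_wraps Maximum number of wraps (default 2).
#' @param start_index 1-based codon position to start from (used when
#'   several expressions are mapped sequentially from one stream).
#' @return A `ge_mapping` object: `expression` (a `ge_expr` tree, or
#'   NULL), `valid`, `codons_consumed`, `wraps_used`, `next_index`, and
#'   `derivation` (data.frame with columns symbol, codon, rule_index).
#' @export
map_chromosome <- function(chrom, grammar, max_wraps = 2L, start_index = 1L) {
  if (is.numeric(chrom)) chrom <- chromosome(chrom)
  codons <- chrom$codons
  n <- length(codons)
  state <- new.env(parent = emptyenv())
  state$i <- as.integer(start_index)
  state$wraps <- 0L
  state$consumed <- 0L
  state$derivation <- list()
  state$failed <- FALSE

  next_codon <- function() {
    if (state$i > n) {
      state$wraps <- state$wraps + 1L
      if (state$wraps > max_wraps) {
        state$failed <- TRUE
        return(NA_integer_)
      }
      state$i <- 1L
    }
    v <- codons[state$i]
    state$i <- state$i + 1L
    state$consumed <- state$consumed + 1L
    v
  }

  expand <- function(sym, depth) {
    if (state$failed) return(NULL)
    if (depth > 400L) {  # runaway recursion guard (deep wrap loops)
      state$failed <- TRUE
      return(NULL)
    }
    if (!is_nonterminal(sym, grammar)) return(sym)
    v <- next_codon()
    if (state$failed) return(NULL)
    nr <- n_rules(grammar, sym)
    rule_idx <- v %% nr
    state$derivation[[length(state$derivation) + 1L]] <-
      list(symbol = sym, codon = v, rule_index = rule_idx)
    rule <- grammar$productions[[sym]][[rule_idx + 1L]]
    parts <- lapply(rule, expand, depth = depth + 1L)
    if (state$failed) return(NULL)
    unlist(parts)
  }

  if (n == 0L) {
    tokens <- NULL
    state$failed <- TRUE
  } else {
    tokens <- expand(grammar$start, 0L)
  }
  deriv <- if (length(state$derivation)) {
    data.frame(symbol = vapply(state$derivation, `[[`, "", "symbol"),
               codon = vapply(state$derivation, `[[`, 0L, "codon"),
               rule_index = vapply(state$derivation, `[[`, 0L, "rule_index"))
  } else {
    data.frame(symbol = character(0), codon = integer(0),
               rule_index = integer(0))
  }
  expr <- if (!state$failed) parse_expression(paste(tokens, collapse = ""))
          else NULL
  structure(list(expression = expr, valid = !state$failed,
                 codons_consumed = state$consumed,
                 wraps_used = state$wraps,
                 next_index = state$i,
                 derivation = deriv),
            class = "ge_mapping")
}

#' @export
print.ge_mapping <- function(x, ...) {
  if (x$valid) {
    cat("valid mapping:", expr_to_string(x$expression), "\n")
    cat(sprintf("  %d codons consumed, %d wraps\n",
                x$codons_consumed, x$wraps_used))
  } else {
    cat("invalid mapping (wrap budget exceeded or empty chromosome)\n")
  }
  invisible(x)
}

# --- expression trees -------------------------------------------------

ge_binop <- function(op, left, right) {
  structure(list(kind = "binop", op = op, left = left, right = right),
            class = "ge_expr")
}
ge_func <- function(fn, arg) {
  structure(list(kind = "func", fn = fn, arg = arg), class = "ge_expr")
}
ge_var <- function(index) {
  structure(list(kind = "var", index = as.integer(index)),
            class = "ge_expr")
}
ge_const <- function(value) {
  structure(list(kind = "const", value = as.double(value)),
            class = "ge_expr")
}

#' Serialize an expression tree to parenthesized infix
#'
#' @param expr A `ge_expr`.
#' @return Character scalar, e.g. `"(x2+cos(x3))"`.
#' @export
expr_to_string <- function(expr) {
  stopifnot(inherits(expr, "ge_expr"))
  switch(expr$kind,
         binop = paste0("(", expr_to_string(expr$left), expr$op,
                        expr_to_string(expr$right), ")"),
         func = paste0(expr$fn, "(", expr_to_string(expr$arg), ")"),
         var = paste0("x", expr$index),
         const = format(expr$value, trim = TRUE))
}

#' @export
print.ge_expr <- function(x, ...) {
  cat(expr_to_string(x), "\n")
  invisible(x)
}

#' Parse a parenthesized infix expression
#'
#' Inverse of [expr_to_string()]: accepts the language generated by the
#' default grammar — variables `x<i>`, decimal constants, unary
#' functions `sin`, `cos`, `exp`, `log`, and fully parenthesized binary
#' `+ - * /`.
#'
#' @param s Character scalar.
#' @return A `ge_expr` tree.
#' @export
parse_expression <- function(s) {
  tokens <- regmatches(s, gregexpr(
    "x[0-9]+|[0-9]+\\.[0-9]+|[0-9]+|sin|cos|exp|log|[()+*/-]", s))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[pos] else NA_character_
  take <- function() {
    t <- peek()
    if (is.na(t)) stop("unexpected end of expression: ", s)
    pos <<- pos + 1L
    t
  }
  parse_expr <- function() {
    t <- take()
    if (t == "(") {
      left <- parse_expr()
      op <- take()
      if (!op %in% c("+", "-", "*", "/")) stop("expected operator, got ", op)
      right <- parse_expr()
      if (take() != ")") stop("expected ')' in ", s)
      return(ge_binop(op, left, right))
    }
    if (t %in% c("sin", "cos", "exp", "log")) {
      if (take() != "(") stop("expected '(' after ", t)
      arg <- parse_expr()
      if (take() != ")") stop("expected ')' after ", t, " argument")
      return(ge_func(t, arg))
    }
    if (grepl("^x[0-9]+$", t)) return(ge_var(sub("^x", "", t)))
    if (grepl("^[0-9.]+$", t)) return(ge_const(t))
    stop("unexpected token '", t, "' in ", s)
  }
  out <- parse_expr()
  if (pos <= length(tokens)) stop("trailing tokens in ", s)
  out
}

#' Evaluate an expression at a point
#'
#' Standard arithmetic with guarded partial operations: division by a
#' denominator smaller than 1e-100 in magnitude, `log` of a
#' non-positive argument, or any intermediate magnitude above 1e100
#' clears the finite flag (the value is still returned for
#' diagnostics).
#'
#' @param expr A `ge_expr`.
#' @param x Numeric vector; `x[i]` binds variable `xi`.
#' @return List with `value` and `finite` (logical).
#' @export
evaluate_expression <- function(expr, x) {
  stopifnot(inherits(expr, "ge_expr"))
  finite <- TRUE
  ev <- function(e) {
    switch(e$kind,
           const = e$value,
           var = {
             if (e$index > length(x)) {
               stop("variable x", e$index, " exceeds input dimension ",
                    length(x))
             }
             x[e$index]
           },
           func = {
             a <- ev(e$arg)
             if (!is.finite(a)) {
               finite <<- FALSE
               return(NaN)
             }
             if (e$fn == "log") {
               if (a <= 0) {
                 finite <<- FALSE
                 return(NaN)
               }
               log(a)
             } else {
               get(e$fn)(a)
             }
           },
           binop = {
             a <- ev(e$left)
             b <- ev(e$right)
             if (e$op == "/") {
               if (is.na(b) || abs(b) < 1e-100) {
                 finite <<- FALSE
                 return(NaN)
               }
             }
             switch(e$op, "+" = a + b, "-" = a - b, "*" = a * b, "/" = a / b)
           })
  }
  value <- ev(expr)
  if (!is.finite(value) || abs(value) > 1e100) finite <- FALSE
  list(value = value, finite = finite)
}

# Vectorized evaluation over the rows of a matrix (columns bind
# x1..xd). Guarded operations yield NaN in the affected rows; callers
# decide whether to penalize (fitness) or clip (dataset transform).
evaluate_expression_matrix <- function(expr, X) {
  clamp <- function(v) {
    v[is.infinite(v) | (!is.na(v) & abs(v) > 1e100)] <- NaN
    v
  }
  ev <- function(e) {
    switch(e$kind,
           const = rep(e$value, nrow(X)),
           var = {
             if (e$index > ncol(X)) {
               stop("variable x", e$index, " exceeds input dimension ",
                    ncol(X))
             }
             X[, e$index]
           },
           func = {
             a <- clamp(ev(e$arg))
             clamp(switch(e$fn,
                          log = ifelse(!is.na(a) & a > 0,
                                       log(pmax(a, 1e-300)), NaN),
                          sin = sin(a), cos = cos(a), exp = exp(a)))
           },
           binop = {
             a <- clamp(ev(e$left))
             b <- clamp(ev(e$right))
             clamp(switch(e$op,
                          "+" = a + b, "-" = a - b, "*" = a * b,
                          "/" = ifelse(!is.na(b) & abs(b) >= 1e-100,
                                       a / b, NaN)))
           })
  }
  clamp(ev(expr))
}
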