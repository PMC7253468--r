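# Shared fixtures: all built in code at test time.

# Draw communities until one has a feasible interior equilibrium.
draw_feasible <- function(params, max_attempts = 200) {
  for (k in seq_len(max_attempts)) {
    x <- generate_chen_cohen(params)
    eq <- tryCatch(suppressWarnings(solve_equilibrium(x)),
                   error = function(e) NULL)
    if (!is.null(eq) && eq$feasible) return(list(matrix = x, eq = eq))
  }
  stop("no feasible draw within the attempt cap")
}

off_diag <- function(A) A[row(A) != col(A)]
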