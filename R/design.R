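#' @name design-letters
#' @title Design letter conventions
#' @description Factor letters follow the classical design-of-experiments
#'   convention: A, B, C, ... skipping I, which is reserved for the identity
#'   word of the defining relation.
#' @keywords internal
NULL

design_letters <- function(k) {
  stopifnot(k <= 25)
  setdiff(LETTERS, "I")[seq_len(k)]
}

# A word is a sorted character vector of letters; multiplication over GF(2)
# is the symmetric difference (letters appearing twice cancel).
word_multiply <- function(w1, w2) {
  sort(union(setdiff(w1, w2), setdiff(w2, w1)))
}

word_string <- function(w) if (length(w) == 0L) "I" else paste(w, collapse = "")

parse_word <- function(s) {
  s <- gsub("\\s", "", s)
  if (identical(s, "I") || !nzchar(s)) return(character(0))
  sort(strsplit(s, "")[[1]])
}

#' Parse a design generator such as "F=ABC"
#'
#' @param s Generator string: generated letter, `=`, product word over the
#'   base letters.
#' @return List with elements `letter` and `word`.
#' @keywords internal
parse_generator <- function(s) {
  parts <- strsplit(gsub("\\s", "", s), "=", fixed = TRUE)[[1]]
  if (length(parts) != 2L || nchar(parts[1]) != 1L) {
    stop("malformed generator word: '", s, "' (expected e.g. \"F=ABC\")",
         call. = FALSE)
  }
  list(letter = parts[1], word = parse_word(parts[2]))
}

#' Minimum-aberration generator catalogue
#'
#' Standard minimum-aberration generators for regular two-level fractional
#' factorial designs, as tabulated in the classical design-of-experiments
#' literature (Box, Hunter & Hunter; Montgomery). Used as the default when
#' [fractional_factorial()] is called without explicit generators. The
#' shipped `2^(8-3)` and `2^(9-3)` entries have resolution IV, so main
#' effects are not aliased with two-factor interactions.
#'
#' @param k Number of factors.
#' @param p Number of generators (the design has `2^(k-p)` runs).
#' @return Character vector of `p` generator words.
#' @export
default_generators <- function(k, p) {
  catalogue <- list(
    "3.1" = c("C=AB"),
    "4.1" = c("D=ABC"),
    "5.1" = c("E=ABCD"),
    "5.2" = c("D=AB", "E=AC"),
    "6.1" = c("F=ABCDE"),
    "6.2" = c("E=ABC", "F=BCD"),
    "6.3" = c("D=AB", "E=AC", "F=BC"),
    "7.1" = c("G=ABCDEF"),
    "7.2" = c("F=ABCD", "G=ABDE"),
    "7.3" = c("E=ABC", "F=BCD", "G=ACD"),
    "7.4" = c("D=AB", "E=AC", "F=BC", "G=ABC"),
    "8.2" = c("G=ABCD", "H=ABEF"),
    "8.3" = c("F=ABC", "G=ABD", "H=BCDE"),
    "8.4" = c("E=BCD", "F=ACD", "G=ABC", "H=ABD"),
    "9.2" = c("H=ACDFG", "J=BCEFG"),
    "9.3" = c("G=ABCD", "H=ACEF", "J=CDEF"),
    "9.4" = c("F=BCDE", "G=ACDE", "H=ABDE", "J=ABCE")
  )
  key <- paste(k, p, sep = ".")
  gens <- catalogue[[key]]
  if (is.null(gens)) {
    stop("no catalogue entry for a 2^(", k, "-", p, ") design; ",
         "supply generators explicitly", call. = FALSE)
  }
  gens
}

#' Alias structure of a regular two-level fractional factorial
#'
#' Computes the defining relation (the group generated by the generator
#' words over GF(2)), the design resolution (length of the shortest
#' non-identity word), and the alias group of every main effect and
#' two-factor interaction up to `max_order`.
#'
#' @param k Number of factors.
#' @param p Number of independent generators.
#' @param generators Character vector of `p` generator words (e.g.
#'   `c("D=AB", "E=AC")`); defaults to the minimum-aberration catalogue.
#' @param max_order Highest interaction order listed in alias groups.
#' @return Object of class `alias_structure` with elements `letters`,
#'   `generators`, `defining_relation` (character), `resolution` (integer)
#'   and `alias_groups` (named list).
#' @examples
#' alias_structure(5, 2, c("D=AB", "E=AC"))
#' @export
alias_structure <- function(k, p, generators = NULL, max_order = 2L) {
  if (is.null(generators)) generators <- default_generators(k, p)
  if (length(generators) != p) {
    stop("need exactly p = ", p, " generators", call. = FALSE)
  }
  letters_k <- design_letters(k)
  base_letters <- letters_k[seq_len(k - p)]
  gen <- lapply(generators, parse_generator)
  gen_letters <- vapply(gen, `[[`, character(1), "letter")
  if (anyDuplicated(gen_letters)) {
    stop("generator words are not independent (duplicated generated letter)",
         call. = FALSE)
  }
  if (!all(gen_letters %in% letters_k[(k - p + 1):k])) {
    stop("generator letters must be the last p design letters (",
         paste(letters_k[(k - p + 1):k], collapse = ", "), ")", call. = FALSE)
  }
  bad <- vapply(gen, function(g) !all(g$word %in% base_letters), logical(1))
  if (any(bad)) {
    stop("generator words must use only base letters ",
         paste(base_letters, collapse = ""), call. = FALSE)
  }
  # full defining words: generated letter times its word
  def_words <- lapply(gen, function(g) sort(c(g$letter, g$word)))
  # group generated by the defining words: products over all non-empty subsets
  relation <- list()
  for (i in seq_along(def_words)) {
    w <- def_words[[i]]
    new <- lapply(relation, word_multiply, w2 = w)
    relation <- c(relation, list(w), new)
  }
  if (length(relation) != 2^p - 1 ||
      anyDuplicated(vapply(relation, word_string, character(1))) ||
      any(lengths(relation) == 0L)) {
    stop("generator words are not independent", call. = FALSE)
  }
  resolution <- min(lengths(relation))

  effects <- c(as.list(letters_k),
               utils::combn(letters_k, 2L, simplify = FALSE))
  alias_groups <- lapply(effects, function(e) {
    al <- lapply(relation, word_multiply, w2 = e)
    al <- al[lengths(al) <= max_order & lengths(al) > 0L]
    sort(vapply(al, word_string, character(1)))
  })
  names(alias_groups) <- vapply(effects, word_string, character(1))

  structure(
    list(letters = letters_k, generators = generators,
         defining_relation = sort(vapply(relation, word_string, character(1))),
         resolution = resolution, alias_groups = alias_groups),
    class = "alias_structure")
}

#' @export
print.alias_structure <- function(x, ...) {
  cat("<alias_structure> resolution", as.roman(x$resolution), "\n")
  cat("  generators:", paste(x$generators, collapse = ", "), "\n")
  cat("  defining relation: I =",
      paste(x$defining_relation, collapse = " = "), "\n")
  aliased <- Filter(length, x$alias_groups)
  if (length(aliased)) {
    cat("  aliases (up to order 2):\n")
    for (nm in names(aliased)) {
      cat("   ", nm, "=", paste(aliased[[nm]], collapse = " = "), "\n")
    }
  }
  invisible(x)
}

new_design_table <- function(df, factors, alias = NULL, center_policy = NULL) {
  attr(df, "factors") <- factors
  attr(df, "alias") <- alias
  attr(df, "center_policy") <- center_policy
  class(df) <- c("design_table", "data.frame")
  df
}

design_meta_cols <- c("run_id", "group", "experiment", "run_order",
                      "replicate", "day", "month", "centerpoint")

#' Factor columns of a design table
#' @param design A `design_table`.
#' @return Character vector of factor column names.
#' @export
design_factors <- function(design) {
  setdiff(names(design), design_meta_cols)
}

#' Coded design matrix
#'
#' @param design A `design_table`.
#' @param include_center Keep centerpoint rows (coded 0)?
#' @return Integer matrix of coded levels (-1, 0, +1), one column per factor.
#' @export
design_matrix <- function(design, include_center = FALSE) {
  rows <- if (include_center) rep(TRUE, nrow(design)) else !design$centerpoint
  as.matrix(as.data.frame(design)[rows, design_factors(design), drop = FALSE])
}

#' Full two-level factorial design
#'
#' All `2^k` combinations of the low/high levels in standard (Yates) order:
#' the first factor alternates fastest. Every factor column is balanced and
#' all pairs of columns are orthogonal.
#'
#' @param factors List of [factor_spec()] objects (1 to 12 factors).
#' @param experiment Optional experiment label stored on each run.
#' @return A `design_table`: one row per run with coded levels (-1/+1) per
#'   factor plus run metadata columns.
#' @examples
#' d <- full_factorial(lycopene_factor_catalogue()[c("growth_time", "temperature")])
#' nrow(d)  # 4
#' @export
full_factorial <- function(factors, experiment = NA_character_) {
  factors <- as_factor_list(factors)
  k <- length(factors)
  if (k < 1L || k > 12L) {
    stop("number of factors must be between 1 and 12, got ", k, call. = FALSE)
  }
  codes <- expand.grid(rep(list(c(-1L, 1L)), k))
  names(codes) <- names(factors)
  build_design(codes, factors, experiment = experiment)
}

#' Regular two-level fractional factorial design
#'
#' Constructs the `2^(k-p)` fraction defined by `p` generator words: the
#' first `k-p` factors form a full factorial in standard order and each
#' generated factor column is the GF(2) product of the base columns named
#' in its generator word. When `generators` is omitted, the built-in
#' minimum-aberration catalogue ([default_generators()]) supplies them.
#'
#' @param factors List of [factor_spec()] objects; factor i is assigned
#'   design letter i (A, B, C, ... skipping I).
#' @param p Number of generators; `k - p >= 2`.
#' @param generators Optional character vector of `p` generator words.
#' @param experiment Optional experiment label.
#' @return List with elements `design` (a `design_table`) and `alias`
#'   (an [alias_structure()], also attached to the design).
#' @examples
#' ff <- fractional_factorial(lycopene_factor_catalogue()[1:5], p = 2,
#'                            generators = c("D=AB", "E=AC"))
#' nrow(ff$design)      # 8
#' ff$alias$resolution  # 3
#' @export
fractional_factorial <- function(factors, p, generators = NULL,
                                 experiment = NA_character_) {
  factors <- as_factor_list(factors)
  k <- length(factors)
  if (k - p < 2L) stop("k - p must be at least 2", call. = FALSE)
  if (k > 12L) stop("at most 12 factors supported", call. = FALSE)
  alias <- alias_structure(k, p, generators)
  base_k <- k - p
  codes <- expand.grid(rep(list(c(-1L, 1L)), base_k))
  names(codes) <- names(factors)[seq_len(base_k)]
  letter_to_col <- stats::setNames(names(factors), alias$letters)
  for (gs in alias$generators) {
    g <- parse_generator(gs)
    col <- Reduce(`*`, lapply(letter_to_col[g$word], function(cn) codes[[cn]]))
    codes[[letter_to_col[[g$letter]]]] <- as.integer(col)
  }
  design <- build_design(codes[names(factors)], factors,
                         alias = alias, experiment = experiment)
  list(design = design, alias = alias)
}

as_factor_list <- function(factors) {
  if (inherits(factors, "factor_spec")) factors <- list(factors)
  stopifnot(all(vapply(factors, inherits, logical(1), "factor_spec")))
  stats::setNames(factors, vapply(factors, `[[`, character(1), "name"))
}

build_design <- function(codes, factors, alias = NULL,
                         experiment = NA_character_) {
  n <- nrow(codes)
  df <- data.frame(
    run_id = sprintf("run%03d", seq_len(n)),
    group = NA_character_,
    experiment = experiment,
    run_order = seq_len(n),
    replicate = 1L,
    day = NA_integer_,
    month = NA_character_,
    centerpoint = FALSE,
    stringsAsFactors = FALSE)
  df <- cbind(df, codes)
  new_design_table(df, factors, alias = alias)
}

#' Append centerpoint runs to a design
#'
#' Centerpoint runs carry coded level 0 for every factor. Quantitative
#' factors take their defined center level; factors without one (and all
#' categorical factors) take the level named in `policy`, the fixed
#' condition a centerpoint run is held at.
#'
#' @param design A `design_table`.
#' @param n_center Number of centerpoint rows to append.
#' @param policy Named list of natural levels for factors lacking a center
#'   level (see [centerpoint_policy()]).
#' @return The extended `design_table`.
#' @export
add_centerpoints <- function(design, n_center, policy = centerpoint_policy()) {
  stopifnot(inherits(design, "design_table"), n_center >= 0)
  if (n_center == 0) return(design)
  factors <- attr(design, "factors")
  missing_center <- vapply(factors, function(f) {
    is.null(f$center) && is.null(policy[[f$name]])
  }, logical(1))
  if (any(missing_center)) {
    stop("no center level or policy entry for factor(s): ",
         paste(names(factors)[missing_center], collapse = ", "), call. = FALSE)
  }
  n0 <- nrow(design)
  cp <- design[rep(1L, n_center), , drop = FALSE]
  cp[design_factors(design)] <- 0L
  cp$centerpoint <- TRUE
  cp$run_id <- sprintf("run%03dc", n0 + seq_len(n_center))
  cp$run_order <- n0 + seq_len(n_center)
  cp$replicate <- seq_len(n_center)
  out <- rbind(as.data.frame(design), as.data.frame(cp))
  rownames(out) <- NULL
  new_design_table(out, factors, alias = attr(design, "alias"),
                   center_policy = policy)
}

#' Randomize the run order of a design
#'
#' Assigns a seeded random permutation to the `run_order` column. The rows
#' themselves (coded and natural levels) are untouched; `run_order` gives
#' the order in which runs are set up and sampled.
#'
#' @param design A `design_table`.
#' @param seed Integer seed; the same seed always yields the same
#'   permutation.
#' @return The design with permuted `run_order`.
#' @export
randomize <- function(design, seed) {
  stopifnot(inherits(design, "design_table"))
  design$run_order <- with_seed(seed, sample.int(nrow(design)))
  design
}

#' Subset the runs of a design table
#'
#' Row subsetting that preserves the design's factor specs, alias
#' structure and centerpoint policy.
#'
#' @param design A `design_table`.
#' @param rows Logical or integer row index.
#' @return A `design_table` with the selected runs.
#' @export
design_subset <- function(design, rows) {
  df <- as.data.frame(design)[rows, , drop = FALSE]
  rownames(df) <- NULL
  new_design_table(df, attr(design, "factors"),
                   alias = attr(design, "alias"),
                   center_policy = attr(design, "center_policy"))
}

#' Natural factor levels of a design
#'
#' Decodes the -1/0/+1 coded levels into natural units using each factor's
#' low/center/high levels and, for code 0 without a center level, the
#' design's centerpoint policy.
#'
#' @param design A `design_table`.
#' @return A data frame with `run_id` and one column per factor in natural
#'   units (numeric for quantitative factors, character for categorical).
#' @export
natural_levels <- function(design) {
  factors <- attr(design, "factors")
  policy <- attr(design, "center_policy")
  out <- data.frame(run_id = design$run_id, stringsAsFactors = FALSE)
  for (fn in design_factors(design)) {
    spec <- factors[[fn]]
    codes <- design[[fn]]
    if (is.null(spec)) next
    out[[fn]] <- vapply(codes, function(cd) {
      v <- decode_level(spec, cd, center_policy = policy[[fn]])
      if (spec$kind == "quantitative") v else as.character(v)
    }, if (spec$kind == "quantitative") numeric(1) else character(1))
  }
  out
}

#' Write a design table to delimited text
#'
#' One row per run with the metadata columns, the coded levels
#' (`<factor>_code`) and the natural levels (`<factor>`).
#'
#' @param design A `design_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  coded <- as.data.frame(design)
  fac <- design_factors(design)
  names(coded)[match(fac, names(coded))] <- paste0(fac, "_code")
  nat <- natural_levels(design)
  out <- cbind(coded, nat[setdiff(names(nat), "run_id")])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

# seeded evaluation that restores the caller's RNG state
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
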