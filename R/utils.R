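#' @importFrom stats cor cov sd var rnorm runif aov anova fisher.test t.test
#'   p.adjust predict quantile cutree hclust dist prcomp varimax promax
#'   setNames complete.cases coef binomial median
#' @importFrom utils combn head
#' @importFrom rlang %||% abort
#' @import tibble
NULL

# Deterministic per-stage seed derived from (master_seed, stage name).
# Keeps stage random streams decoupled: consuming more draws in one stage
# never shifts another stage's stream. Result is kept below 2^31 - 1.
stage_seed <- function(master_seed, stage) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  codes <- utf8ToInt(stage)
  h <- (master_seed %% 2147483647) + 1
  for (c in codes) h <- (h * 31 + c) %% 2147483629
  as.integer(h)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Jaccard similarity between two membership sets
#'
#' \eqn{|A \cap B| / |A \cup B|}; the similarity used to score bootstrap
#' cluster stability.
#'
#' @param a,b Vectors interpreted as sets (duplicates ignored).
#' @return A number in \[0, 1\]; 1 when both sets are empty.
#' @export
jaccard_similarity <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}

# Accept a data frame (participant_id column dropped) or matrix of items;
# return a numeric matrix with rownames = participant ids when available.
as_item_matrix <- function(items) {
  if (is.matrix(items)) {
    storage.mode(items) <- "double"
    return(items)
  }
  stopifnot(is.data.frame(items))
  ids <- NULL
  if ("participant_id" %in% names(items)) {
    ids <- as.character(items$participant_id)
    items <- items[setdiff(names(items), "participant_id")]
  }
  m <- as.matrix(items)
  storage.mode(m) <- "double"
  if (!is.null(ids)) rownames(m) <- ids
  m
}

check_scalar_prop <- function(x, name, lo = 0, hi = 1, open_hi = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo ||
      (if (open_hi) x >= hi else x > hi)) {
    abort(sprintf("`%s` must be a single number in [%s, %s%s", name, lo,
                  hi, if (open_hi) ")" else "]"))
  }
  invisible(x)
}
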