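#' Construct a fitness table
#'
#' A `fitness_table` is a validated long-format data frame of replicate-level
#' trait measurements from a mutation-accumulation experiment, with columns
#' `line_id`, `group` (one of `"ancestor"`, `"control"`, `"MA"`), `trait`,
#' `block`, `replicate` and `value`, plus experiment-level metadata stored as
#' attributes: `G` (number of cell generations of accumulation) and an
#' optional `units` map per trait.
#'
#' @param records data frame with columns `line_id`, `group`, `trait`,
#'   `block` (may be `NA`), `replicate`, `value`.
#' @param G number of cell generations of mutation accumulation (default 994,
#'   i.e. 70 single-cell bottlenecks at 14.2 generations per transfer).
#' @param units optional named character vector mapping trait to units.
#' @param traits allowed trait names; defaults to the eight fitness
#'   components of the reference design.
#' @param drop_na drop records with missing `value` (with a message) rather
#'   than erroring.
#' @return a `fitness_table` (data.frame subclass).
#' @export
fitness_table <- function(records, G = 994, units = NULL,
                          traits = .ma_traits, drop_na = TRUE) {
  required <- c("line_id", "group", "trait", "replicate", "value")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  if (!"block" %in% names(records)) records$block <- NA_integer_
  records$block <- as.integer(records$block)
  records <- records[c("line_id", "group", "trait", "block", "replicate", "value")]
  records$line_id <- as.character(records$line_id)
  records$group <- as.character(records$group)
  records$trait <- as.character(records$trait)
  records$value <- as.numeric(records$value)

  bad_group <- setdiff(unique(records$group), .ma_groups)
  if (length(bad_group))
    stop("unknown group label(s): ", paste(bad_group, collapse = ", "))
  bad_trait <- setdiff(unique(records$trait), traits)
  if (length(bad_trait))
    stop("unknown trait(s): ", paste(bad_trait, collapse = ", "))

  n_na <- sum(is.na(records$value))
  if (n_na > 0) {
    if (!drop_na) stop(n_na, " records with missing value")
    message("dropping ", n_na, " record(s) with missing value")
    records <- records[!is.na(records$value), , drop = FALSE]
  }
  if (any(!is.finite(records$value)))
    stop("non-finite trait values are not allowed")
  germ <- records$trait == "spore_germination"
  if (any(germ) && (any(records$value[germ] < 0) || any(records$value[germ] > 1)))
    stop("spore_germination values must lie in [0, 1] (proportion scale)")

  key <- paste(records$line_id, records$trait, records$block,
               records$replicate, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (line_id, trait, block, replicate) record(s): ",
         records$line_id[duplicated(key)][1])

  # every MA/control trait must have ancestor replicates to normalise against
  for (tr in unique(records$trait[records$group != "ancestor"])) {
    if (!any(records$trait == tr & records$group == "ancestor"))
      stop("trait '", tr, "' has no ancestor replicates")
  }

  rownames(records) <- NULL
  structure(records, G = G, units = units, traits = traits,
            class = c("fitness_table", "data.frame"))
}

#' @export
print.fitness_table <- function(x, ...) {
  cat("fitness_table: ", nrow(x), " records, ",
      length(unique(x$trait)), " trait(s), G = ", attr(x, "G"), "\n", sep = "")
  cat("  lines: ", length(unique(x$line_id[x$group == "MA"])), " MA, ",
      length(unique(x$line_id[x$group == "control"])), " control\n", sep = "")
  print(head(as.data.frame(x)), ...)
  invisible(x)
}

#' Read a fitness table from CSV/TSV
#'
#' Expects a UTF-8 header `line_id,group,trait,block,replicate,value`
#' (`block` optional). Rows with value `NA` are dropped with a message;
#' malformed rows and duplicate records raise errors naming the offender.
#'
#' @param path file path; `.tsv`/`.txt` files are read tab-separated.
#' @param G,units,traits passed to [fitness_table()].
#' @return a [fitness_table()].
#' @export
read_fitness_table <- function(path, G = 994, units = NULL, traits = .ma_traits) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  fitness_table(df, G = G, units = units, traits = traits)
}

#' Write a fitness table to CSV
#'
#' Values are written with full precision (15 significant digits) so that a
#' write-then-read round trip reproduces the table.
#'
#' @param table a [fitness_table()].
#' @param path output path.
#' @export
write_fitness_table <- function(table, path) {
  df <- as.data.frame(table)
  df$value <- formatC(df$value, digits = 15, format = "g")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert measurements to relative fitness
#'
#' Divides every value of a trait by the mean of the ancestor replicates for
#' that trait, so that the ancestor mean of the transformed values is exactly
#' 1. By default ancestor replicates are pooled across assay blocks before
#' taking the mean (block effects having been screened with
#' [kruskal_wallis_blocks()]); `per_block = TRUE` normalises each block by
#' its own ancestor mean instead.
#'
#' @param table a [fitness_table()].
#' @param trait trait name, or `NULL` to transform every trait present.
#' @param per_block normalise within blocks rather than pooling.
#' @return a [fitness_table()] on the relative-fitness scale.
#' @export
relative_fitness <- function(table, trait = NULL, per_block = FALSE) {
  traits <- if (is.null(trait)) unique(table$trait) else trait
  out <- as.data.frame(table)
  for (tr in traits) {
    anc <- out$group == "ancestor" & out$trait == tr
    if (!any(anc)) stop("no ancestor replicates for trait '", tr, "'")
    rows <- out$trait == tr
    if (per_block && !all(is.na(out$block[rows]))) {
      for (b in unique(out$block[rows])) {
        bi <- rows & (out$block %in% b)
        m <- mean(out$value[anc & (out$block %in% b)])
        if (!is.finite(m) || m <= 0)
          stop("ancestor mean for trait '", tr, "' block ", b,
               " is not positive; relative scale undefined")
        out$value[bi] <- out$value[bi] / m
      }
    } else {
      m <- mean(out$value[anc])
      if (m <= 0)
        stop("ancestor mean for trait '", tr,
             "' is not positive; relative scale undefined")
      out$value[rows] <- out$value[rows] / m
    }
  }
  fitness_table(out, G = attr(table, "G"), units = attr(table, "units"),
                traits = attr(table, "traits") %||% .ma_traits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-line trait values
#'
#' Collapses replicates to one value per line for MA and control groups (the
#' mean across that line's replicates), leaving ancestor replicates as-is.
#'
#' @param table a [fitness_table()].
#' @param trait trait name.
#' @return list with `ancestor` (replicate values), `control` and `MA`
#'   (named per-line means).
#' @export
line_values <- function(table, trait) {
  d <- table[table$trait == trait, , drop = FALSE]
  if (!nrow(d)) stop("no records for trait '", trait, "'")
  per_line <- function(g) {
    dd <- d[d$group == g, , drop = FALSE]
    if (!nrow(dd)) return(setNames(numeric(0), character(0)))
    vapply(split(dd$value, dd$line_id), mean, numeric(1))
  }
  list(ancestor = d$value[d$group == "ancestor"],
       control = per_line("control"),
       MA = per_line("MA"))
}

#' Group summaries of a fitness trait
#'
#' Sample mean and variance (divisor n-1) per group: MA and control groups
#' are summarised over line means (replicates averaged within line first),
#' the ancestor over its individual replicates.
#'
#' @param table a [fitness_table()].
#' @param trait trait name, or `NULL` for all traits present.
#' @param level `"line_mean"` (default) or `"replicate"` (no within-line
#'   averaging for MA/control).
#' @return data frame with columns trait, group, n, mean, var (var is `NA`
#'   when n < 2, never a spurious 0).
#' @export
summarize_fitness <- function(table, trait = NULL, level = c("line_mean", "replicate")) {
  level <- match.arg(level)
  traits <- if (is.null(trait)) unique(table$trait) else trait
  rows <- lapply(traits, function(tr) {
    vals <- if (level == "line_mean") {
      lv <- line_values(table, tr)
      list(ancestor = lv$ancestor, control = unname(lv$control), MA = unname(lv$MA))
    } else {
      d <- table[table$trait == tr, , drop = FALSE]
      split(d$value, factor(d$group, levels = .ma_groups))
    }
    do.call(rbind, lapply(names(vals), function(g) {
      v <- vals[[g]]
      if (!length(v)) return(NULL)
      data.frame(trait = tr, group = g, n = length(v), mean = mean(v),
                 var = if (length(v) >= 2) var(v) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Line-by-trait matrix of relative fitness means
#'
#' @param table a [fitness_table()] (relative scale expected).
#' @param group group to extract (default `"MA"`).
#' @return numeric matrix, lines in rows, traits in columns.
#' @export
line_trait_matrix <- function(table, group = "MA") {
  traits <- unique(table$trait)
  lines <- sort(unique(table$line_id[table$group == group]))
  m <- matrix(NA_real_, length(lines), length(traits),
              dimnames = list(lines, traits))
  for (tr in traits) {
    lv <- line_values(table, tr)[[group]]
    m[names(lv), tr] <- lv
  }
  m
}
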