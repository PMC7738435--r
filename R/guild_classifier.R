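#' Guild rule set
#'
#' Lineage keywords used to recognize known syntrophs and known methanogens
#' by their phylogenetic affiliation. Matching is case-insensitive substring
#' search over the full SILVA-style lineage string, so a keyword may sit at
#' any rank (family "Syntrophaceae" and genus "Smithella" both work).
#'
#' @param syntrophs character vector of lineage keywords.
#' @param methanogens character vector of lineage keywords; must be disjoint
#'   from `syntrophs`.
#' @return An object of class `guild_rules`.
#' @export
guild_rules <- function(syntrophs, methanogens) {
  syntrophs <- unique(trimws(as.character(syntrophs)))
  methanogens <- unique(trimws(as.character(methanogens)))
  syntrophs <- syntrophs[nzchar(syntrophs)]
  methanogens <- methanogens[nzchar(methanogens)]
  both <- intersect(tolower(syntrophs), tolower(methanogens))
  if (length(both) > 0)
    stop("keyword(s) in both syntroph and methanogen lists: ",
         paste(both, collapse = ", "))
  structure(list(syntrophs = syntrophs, methanogens = methanogens),
            class = "guild_rules")
}

#' @export
print.guild_rules <- function(x, ...) {
  cat("Guild rules: ", length(x$syntrophs), " syntroph and ",
      length(x$methanogens), " methanogen lineage keywords\n", sep = "")
  invisible(x)
}

#' Packaged default guild rules
#'
#' Reads the editable keyword file shipped with the package
#' (`extdata/guild_rules.txt`), covering the syntrophic genera/families and
#' methanogen genera commonly reported from sludge fermenters and anaerobic
#' digesters.
#'
#' @return A [guild_rules] object.
#' @export
default_rules <- function() {
  read_guild_rules(system.file("extdata", "guild_rules.txt",
                               package = "egmb", mustWork = TRUE))
}

#' Read / write a guild rule file
#'
#' Plain text, one keyword per line, under `[syntrophs]` and `[methanogens]`
#' section headers; `#` starts a comment.
#'
#' @param path rule file.
#' @return A [guild_rules] object.
#' @export
read_guild_rules <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  section <- NA_character_
  out <- list(syntrophs = character(), methanogens = character())
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- sub("^\\[(.*)\\]$", "\\1", ln)
      if (!section %in% names(out))
        stop("unknown section [", section, "] in ", path)
    } else {
      if (is.na(section))
        stop("keyword '", ln, "' before any section header in ", path)
      out[[section]] <- c(out[[section]], ln)
    }
  }
  guild_rules(out$syntrophs, out$methanogens)
}

#' @rdname read_guild_rules
#' @param rules a [guild_rules] object to serialize.
#' @export
write_guild_rules <- function(rules, path) {
  stopifnot(inherits(rules, "guild_rules"))
  writeLines(c("[syntrophs]", rules$syntrophs, "",
               "[methanogens]", rules$methanogens), path)
  invisible(path)
}

match_keyword <- function(taxonomy, keywords) {
  lt <- tolower(taxonomy)
  for (kw in keywords)
    if (grepl(tolower(kw), lt, fixed = TRUE)) return(kw)
  NA_character_
}

#' Classify one OTU into a microbial guild
#'
#' Four guilds are assigned with the precedence taxonomy-before-rate:
#' a syntroph keyword match wins over a methanogen match, and both win over
#' the growth-rate sign rule. For OTUs matching neither list, a defined net
#' growth rate decides: `mu < 0` means the taxon is being decomposed faster
#' than it grows and is a feed-sludge (WAS) associated population; `mu >= 0`
#' means a maintained or growing population, a fermenter. OTUs with no
#' taxonomy match and no defined rate (washed out, or absent everywhere) are
#' `unclassified`. Archaeal lineages that miss the methanogen list fall
#' through to the sign rule with a warning, since no rule is defined for
#' non-methanogen archaea.
#'
#' @param taxonomy lineage string.
#' @param record a `growth_rate_record` from [compute_growth_rate] (or any
#'   list with `mu` and `status`).
#' @param rules a [guild_rules] object.
#' @return list with `guild` (one of `"syntroph"`, `"methanogen"`,
#'   `"fermenter"`, `"was_associated"`, `"unclassified"`) and `rule_fired`
#'   (text describing the decisive rule).
#' @export
classify_otu <- function(taxonomy, record, rules) {
  stopifnot(inherits(rules, "guild_rules"))
  kw <- match_keyword(taxonomy, rules$syntrophs)
  if (!is.na(kw))
    return(list(guild = "syntroph",
                rule_fired = paste0("lineage contains '", kw, "'")))
  kw <- match_keyword(taxonomy, rules$methanogens)
  if (!is.na(kw))
    return(list(guild = "methanogen",
                rule_fired = paste0("lineage contains '", kw, "'")))
  if (grepl("archaea", taxonomy, ignore.case = TRUE))
    warning("archaeal lineage without a methanogen match falls through to ",
            "the growth-rate sign rule: ", taxonomy)
  mu <- record$mu
  if (is.null(mu) || is.na(mu))
    return(list(guild = "unclassified",
                rule_fired = paste0("no taxonomy match; status ",
                                    record$status)))
  if (mu < 0)
    list(guild = "was_associated", rule_fired = "net growth rate < 0")
  else
    list(guild = "fermenter", rule_fired = "net growth rate >= 0")
}

#' Classify every OTU of a growth-rate table
#'
#' @param df growth-rate data.frame from [compute_growth_table].
#' @param rules a [guild_rules]; defaults to the packaged rule file.
#' @return `df` with `guild` and `rule_fired` columns appended.
#' @export
classify_guilds <- function(df, rules = default_rules()) {
  res <- lapply(seq_len(nrow(df)), function(i)
    classify_otu(df$taxonomy[i],
                 list(mu = df$mu[i], status = df$status[i]), rules))
  df$guild <- vapply(res, `[[`, character(1L), "guild")
  df$rule_fired <- vapply(res, `[[`, character(1L), "rule_fired")
  df
}

#' Representative OTUs per guild
#'
#' Selects the most abundant OTUs within each guild, ranked by reactor
#' relative abundance, for compact reporting of guild-level growth-rate
#' patterns.
#'
#' @param df classified growth-rate data.frame from [classify_guilds].
#' @param n how many OTUs to keep per guild (default 8).
#' @return subset of `df`, ordered by guild then descending `p_reactor`.
#' @export
top_representatives <- function(df, n = 8L) {
  stopifnot(all(c("guild", "p_reactor") %in% names(df)))
  parts <- split(df, df$guild)
  picked <- lapply(parts, function(g) {
    g <- g[order(-g$p_reactor), , drop = FALSE]
    utils::head(g, n)
  })
  out <- do.call(rbind, picked)
  rownames(out) <- NULL
  out
}
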