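#' T-plots, record tables and the packaged reference pair tables
#'
#' A T-plot shows degradome tag abundance along a transcript with the
#' called cleavage site marked; a clear solitary peak at the predicted
#' site is the visual signature of miRNA-guided slicing. The package
#' also ships the curated tables of significant miRNA-mRNA cleavage
#' pairs from the mulberry drought degradome study - 72 pairs in the
#' control library (CL) and 63 in the drought library (DL), all sites in
#' the CDS - as machine-readable fixtures used throughout the test
#' suite.
#'
#' @name reporting_fixtures
NULL

#' Render a T-plot of a degradome profile
#'
#' @param counts named integer vector (profile of one transcript).
#' @param site called cleavage site (must be an occupied position).
#' @param mode `"tsv"` returns/writes the (position, abundance, is_site)
#'   table; `"figure"` writes a PNG.
#' @param file output path (required for `mode = "figure"`; optional TSV
#'   path otherwise).
#' @param main plot title (e.g. "miRNA x transcript").
#' @return the T-plot data frame, invisibly for figure mode.
#' @export
render_tplot <- function(counts, site, mode = c("tsv", "figure"),
                         file = NULL, main = "") {
  mode <- match.arg(mode)
  if (!length(counts)) stop("empty degradome profile")
  pos <- as.integer(names(counts))
  df <- data.frame(position = pos, abundance = as.integer(counts),
                   is_site = pos == site)
  df <- df[order(df$position), , drop = FALSE]
  rownames(df) <- NULL
  if (!any(df$is_site)) stop("site ", site, " not present in profile")
  if (mode == "tsv") {
    if (!is.null(file))
      write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
    return(df)
  }
  if (is.null(file)) stop("figure mode needs a file path")
  grDevices::png(file, width = 800, height = 500)
  on.exit(grDevices::dev.off())
  plot(df$position, df$abundance, type = "h", lwd = 2,
       col = ifelse(df$is_site, "red", "grey30"),
       xlab = "position in transcript (nt)", ylab = "raw tag count",
       main = main)
  graphics::points(site, df$abundance[df$is_site], col = "red", pch = 16)
  invisible(df)
}

#' Load a packaged reference pair table
#'
#' @param library `"CL"` (control) or `"DL"` (drought).
#' @return data frame with columns `miRNA`, `Target`, `C.Site`,
#'   `Location`, `Score`, `Category`, `TP100M`, `P.Value`.
#' @export
load_fixture <- function(library = c("CL", "DL")) {
  library <- match.arg(library)
  path <- system.file("extdata",
                      sprintf("targets_%s.tsv", tolower(library)),
                      package = "paredeg", mustWork = TRUE)
  load_fixture_path(path)
}

# Parse and validate a pair table at an explicit path.
load_fixture_path <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("miRNA", "Target", "C.Site", "Location", "Score", "Category",
            "TP100M", "P.Value")
  if (!identical(names(df), need))
    stop("malformed fixture ", path, ": columns ",
         paste(names(df), collapse = ", "))
  for (col in c("C.Site", "Category", "TP100M")) {
    bad <- which(is.na(suppressWarnings(as.integer(df[[col]]))))
    if (length(bad))
      stop("malformed fixture ", path, ": non-integer ", col,
           " at row ", bad[1])
    df[[col]] <- as.integer(df[[col]])
  }
  for (col in c("Score", "P.Value")) {
    bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad))
      stop("malformed fixture ", path, ": non-numeric ", col,
           " at row ", bad[1])
    df[[col]] <- as.numeric(df[[col]])
  }
  df
}

#' miRNA family of a miRNA name
#'
#' Strips trailing variant letters, copy segments and arm suffixes:
#' `mno-miR156c` and `mno-miR156g` belong to family `mno-miR156`;
#' `mno-miRn74a-1-3p` belongs to `mno-miRn74`.
#'
#' @param x character vector of miRNA names.
#' @return character vector of family names.
#' @export
mirna_family <- function(x) {
  m <- regmatches(x, regexpr("^[A-Za-z]+-miRn?\\d+", x))
  out <- x
  has <- grepl("^[A-Za-z]+-miRn?\\d+", x)
  out[has] <- m
  out
}

# Arm (3p/5p) of a miRNA name, NA when not annotated.
mirna_arm <- function(x) {
  arm <- rep(NA_character_, length(x))
  hit <- grepl("-[35]p$", x)
  arm[hit] <- substr(x[hit], nchar(x[hit]) - 1, nchar(x[hit]))
  arm
}

#' Grouped counts of a pair table
#'
#' @param fixture data frame from [load_fixture()] (or any record table
#'   with `miRNA` and `Category` columns).
#' @param group_by `"category"` or `"mirna_family"`.
#' @return data frame `group`, `n`.
#' @export
summarize_fixture <- function(fixture, group_by = c("category", "mirna_family")) {
  group_by <- match.arg(group_by)
  if (!nrow(fixture))
    return(data.frame(group = character(0), n = integer(0)))
  key <- switch(group_by,
                category = as.character(fixture$Category),
                mirna_family = mirna_family(fixture$miRNA))
  tab <- table(key)
  data.frame(group = names(tab), n = as.integer(tab),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a record table in the published column layout
#'
#' @param records data frame from [call_targets()].
#' @param file output TSV path.
#' @return the reshaped data frame, invisibly.
#' @export
write_record_table <- function(records, file) {
  out <- data.frame(miRNA = records$mirna, Target = records$target,
                    C.Site = records$c_site, Location = records$location,
                    Score = sprintf("%.1f", records$score),
                    Category = records$category,
                    TP100M = records$tp100m, P.Value = records$p_value,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
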