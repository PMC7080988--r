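# Reading and writing the .bnet logical-model text format:
#   targets, factors
#   NODE, expression
# with the operators !, & and |.

#' Read a Boolean network from a .bnet file
#'
#' @param con a file path, connection, or character vector of lines.
#' @param name network label; defaults to the file name when reading a path.
#' @return a \code{boolean_network}.
#' @details Comment lines starting with \code{#} and blank lines are
#'   skipped. The header line \code{targets, factors} is required. Factor
#'   names must all be declared as targets; an undeclared factor is an
#'   error naming the offending node, a malformed line an error with its
#'   line number.
#' @examples
#' net <- read_bnet(c("targets, factors", "A, A", "B, A & !B"))
#' # the bundled EndMT model ships as a .bnet file too
#' endmt <- read_bnet(system.file("extdata", "endmt.bnet",
#'                                package = "endmtbn"))
#' @export
read_bnet <- function(con, name = NULL) {
  if (is.character(con) && length(con) == 1L && !grepl("\n", con) &&
      file.exists(con)) {
    if (is.null(name)) name <- sub("\\.bnet$", "", basename(con))
    lines <- readLines(con, warn = FALSE)
  } else if (is.character(con)) {
    lines <- unlist(strsplit(con, "\n", fixed = TRUE))
  } else {
    lines <- readLines(con, warn = FALSE)
  }
  if (is.null(name)) name <- "network"
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop("empty .bnet input", call. = FALSE)
  header <- lines[idx[1]]
  if (!grepl("^\\s*targets\\s*,\\s*factors\\s*$", header, ignore.case = TRUE))
    stop(sprintf("line %d: expected header 'targets, factors', got '%s'",
                 idx[1], trimws(header)), call. = FALSE)
  body <- idx[-1]
  targets <- character(0)
  exprs <- character(0)
  for (i in body) {
    ln <- lines[i]
    m <- regexpr(",", ln, fixed = TRUE)
    if (m == -1L)
      stop(sprintf("line %d: expected 'target, expression', got '%s'",
                   i, trimws(ln)), call. = FALSE)
    tgt <- trimws(substr(ln, 1L, m - 1L))
    ex <- trimws(substr(ln, m + 1L, nchar(ln)))
    if (!grepl("^[A-Za-z_][A-Za-z0-9_]*$", tgt))
      stop(sprintf("line %d: invalid target name '%s'", i, tgt),
           call. = FALSE)
    if (ex == "")
      stop(sprintf("line %d: empty expression for '%s'", i, tgt),
           call. = FALSE)
    targets <- c(targets, tgt)
    exprs <- c(exprs, ex)
  }
  names(exprs) <- targets
  # boolean_network() itself rejects undeclared factors, naming them
  boolean_network(exprs, name = name)
}

#' Write a Boolean network to the .bnet format
#'
#' @param network a \code{boolean_network}.
#' @param con optional file path or connection; if omitted the lines are
#'   returned as a character vector.
#' @return the .bnet lines, invisibly when written to a file/connection.
#' @details \code{read_bnet(write_bnet(net))} reproduces \code{net}'s truth
#'   tables exactly; expressions are re-rendered with minimal parentheses,
#'   so the text may differ while the semantics round-trip.
#' @export
write_bnet <- function(network, con = NULL) {
  lines <- c("targets, factors",
             vapply(network$nodes, function(nd)
               paste0(nd, ", ", network$rules[[nd]]$expression),
               character(1)))
  if (is.null(con)) return(unname(lines))
  writeLines(lines, con)
  invisible(unname(lines))
}
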