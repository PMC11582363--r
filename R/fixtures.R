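#' Packaged worked-example tables
#'
#' Three small information systems are shipped with the package, transcribed
#' cell-for-cell from the worked examples the pipeline is demonstrated on:
#'
#' * `"table1"` — a 5-patient system with two clinical columns, three
#'   gene-expression probes and a survival-period decision column `d`
#'   (months).  The printed source runs its first two columns together; as
#'   rendered, `a1` is the 45/35/65/36/64 column and `a2` the 1/2/1/1/2
#'   column, and the fixture stores exactly that rendering.
#' * `"table3"` — the same five patients after feature reduction, with the
#'   survival column replaced by a 0/1 `event` indicator.
#' * `"table11"` — a 20-patient sample with six clinical attributes,
#'   seventeen gene-expression probes, the Dukes-stage decision `d`
#'   (0--3) and an `event` column.  `DFS` (disease-free survival, months)
#'   doubles as the follow-up-time attribute.
#'
#' @param name One of `"table1"`, `"table3"`, `"table11"`.
#' @return An [information_system()].
#' @examples
#' crc_fixture("table11")
#' @export
crc_fixture <- function(name) {
  if (length(name) != 1L || !name %in% c("table1", "table3", "table11"))
    stop("unknown fixture '", paste(name, collapse = ","),
         "'; available: table1, table3, table11", call. = FALSE)
  path <- system.file("extdata", paste0(name, ".csv"), package = "rsfas",
                      mustWork = TRUE)
  switch(name,
    table1 = read_information_system(path, decision = "d",
                                     categorical = "a2"),
    table3 = read_information_system(path, event = "event",
                                     categorical = "a2"),
    table11 = read_information_system(
      path, decision = "d", time = "DFS", event = "event",
      categorical = c("Gender", "Location", "AdjRadio", "AdjChem")))
}

# printed value ranges of the seventeen gene-expression probes the sample
# dataset carries; reused by the synthetic generator
gene_ranges <- function() {
  m <- rbind(
    G27   = c(3.31, 5.32),
    G55   = c(2.76, 7.26),
    G64   = c(3.41, 6.82),
    G108  = c(2.79, 6.01),
    G171  = c(5.23, 8.21),
    G278  = c(4.00, 5.31),
    G373  = c(3.32, 10.35),
    G404  = c(5.01, 8.31),
    G669  = c(2.86, 5.09),
    G701  = c(3.51, 6.56),
    G1269 = c(3.38, 6.23),
    G1271 = c(3.93, 6.51),
    G1273 = c(2.91, 8.03),
    G1333 = c(4.03, 7.61),
    G1339 = c(3.95, 7.81),
    G1509 = c(3.45, 5.75),
    G1612 = c(3.99, 8.52))
  colnames(m) <- c("lo", "hi")
  m
}
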