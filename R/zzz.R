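.mirpipe <- new.env(parent = emptyenv())

.onLoad <- function(libname, pkgname) {
  ext <- system.file("extdata", package = pkgname)
  st <- utils::read.delim(file.path(ext, "stack_energies.tsv"),
                          row.names = 1, check.names = FALSE)
  stack <- as.matrix(st)
  storage.mode(stack) <- "double"
  lp <- utils::read.delim(file.path(ext, "loop_params.tsv"))
  params <- stats::setNames(as.numeric(lp$value), lp$param)
  assign("stack", stack, envir = .mirpipe)
  assign("loop_params", params, envir = .mirpipe)
  invisible()
}
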