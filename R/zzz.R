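.onLoad <- function(libname, pkgname) {
  # register the module-framework S3 methods so dispatch also works when the
  # generics are reached from outside the namespace (tests, interactive use)
  ns <- asNamespace(pkgname)
  for (gen in c("fwd", "mod_profile", "mod_params", "mod_fuse")) {
    for (nm in ls(ns, pattern = paste0("^", gen, "\\."))) {
      cls <- sub(paste0("^", gen, "\\."), "", nm)
      registerS3method(gen, cls, get(nm, envir = ns), envir = ns)
    }
  }
  invisible()
}
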