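// Pin the BLAS thread count.  Heatmap training issues many small-to-
// medium GEMMs; letting OpenBLAS fan out across detected cores causes
// oversubscription on constrained machines and makes reductions
// nondeterministic, so the package pins BLAS to one thread on load.
// The symbol is resolved dynamically so linking works with any BLAS.

#include <Rcpp.h>
#ifndef _WIN32
#include <dlfcn.h>
#endif

// [[Rcpp::export(name = ".set_blas_threads_cpp")]]
bool set_blas_threads_cpp(int n) {
#ifndef _WIN32
  typedef void (*setter)(int);
  void* sym = dlsym(RTLD_DEFAULT, "openblas_set_num_threads");
  if (sym == nullptr) sym = dlsym(RTLD_DEFAULT, "goto_set_num_threads");
  if (sym != nullptr) {
    reinterpret_cast<setter>(sym)(n);
    return true;
  }
#endif
  return false;
}
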