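# Vectorised elementwise kernels (instance norm, pooling, scatter adds)
# dominate after the BLAS GEMMs; build them for the host CPU.
CXXFLAGS += -O3 -funroll-loops -ffast-math -march=native
CXX17FLAGS += -O3 -funroll-loops -ffast-math -march=native
PKG_LIBS = $(LAPACK_LIBS) $(BLAS_LIBS) $(FLIBS)
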