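CXX_STD = CXX17
# The attention softmax / ELU hot loops rely on auto-vectorization. Site
# makefiles re-define CXXFLAGS after this file is read, so the flags are
# appended per-target (resolved at rule execution, after all includes).
%.o: CXXFLAGS += -O3 -ffast-math -funroll-loops -march=x86-64-v3
%.o: CXX17FLAGS += -O3 -ffast-math -funroll-loops -march=x86-64-v3
PKG_LIBS = $(LAPACK_LIBS) $(BLAS_LIBS) $(FLIBS)
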