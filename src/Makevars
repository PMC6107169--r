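RHDF5LIB_INCLUDE = $(shell "${R_HOME}/bin/Rscript" -e 'cat(system.file("include", package = "Rhdf5lib"))')
RHDF5_LIBS = $(shell "${R_HOME}/bin/Rscript" -e 'Rhdf5lib::pkgconfig("PKG_C_LIBS")')
PKG_CPPFLAGS = -I"$(RHDF5LIB_INCLUDE)"
PKG_LIBS = $(RHDF5_LIBS)
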