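>RBD_exemplar synthetic RAS-binding-domain exemplar
RPVWFPSIATHMIPWVSRGPMFTGTHINTYCPFHICDGIPVDHDAVWIIIHDHYRDDLKV
LVGDPMVMTQEYGDN
>CC_SAM_exemplar synthetic CC-SAM exemplar
NDTCRETNCAERAPSKYEGQTQDCPTAGRGFTRTVTARKEPLYDNPDITAMRHPDFQNLG
HYLSQAWTVF
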