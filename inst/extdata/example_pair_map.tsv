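pair_id	left	right	zone
P001	L001	R001	primary
P002	L002	R002	unimodal
P003	L003	R003	heteromodal
P004	L004	R004	paralimbic
P005	L005	R005	limbic
P006	L006	R006	subcortical
P007	L007	R007	primary
P008	L008	R008	unimodal
P009	L009	R009	heteromodal
P010	L010	R010	paralimbic
P011	L011	R011	limbic
P012	L012	R012	subcortical
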