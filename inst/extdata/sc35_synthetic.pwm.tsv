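#name=SC35_synthetic threshold=2.383
A	-0.062	-0.234	-0.597	-0.623	-0.246	-0.490	-0.405	-0.893
C	-0.232	-0.870	1.193	1.113	-0.899	1.139	-0.677	-0.178
G	1.266	0.908	-0.893	-0.715	-0.519	-0.621	-0.407	1.123
T	-0.557	0.133	-0.070	-0.472	1.005	-0.826	1.277	-0.690
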