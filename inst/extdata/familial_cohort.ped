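FML001 II.1 0 0 1 2
FML002 II.1 0 0 1 2
FML003 II.1 0 0 1 2
FML004 II.1 0 0 1 2
FML005 II.1 0 0 1 2
FML006 II.1 0 0 1 2
FML007 II.1 0 0 1 2
FML008 II.1 0 0 1 2
FML009 II.1 0 0 1 2
FML010 II.1 0 0 1 2
FML011 II.1 0 0 1 2
FML012 II.1 0 0 1 2
FML013 II.1 0 0 1 2
FML014 II.1 0 0 1 2
FML015 II.1 0 0 1 2
FML016 II.1 0 0 1 2
FML017 II.1 0 0 1 2
FML018 II.1 0 0 1 2
FML019 II.1 0 0 1 2
FML020 II.1 0 0 1 2
FML021 II.1 0 0 1 2
FML022 II.1 0 0 1 2
FML023 II.1 0 0 1 2
FML024 II.1 0 0 1 2
FML025 II.1 0 0 1 2
FML026 II.1 0 0 1 2
FML027 II.1 0 0 1 2
FML028 II.1 0 0 1 2
FML029 II.1 0 0 1 2
FML030 II.1 0 0 1 2
FML030 II.2 0 0 2 2
FML030 II.3 0 0 1 1
FML031 II.1 0 0 1 2
FML031 II.2 0 0 2 2
FML031 II.3 0 0 1 1
FML032 II.1 0 0 1 2
FML032 II.2 0 0 2 2
FML032 II.3 0 0 1 1
FML033 II.1 0 0 1 2
FML033 II.2 0 0 2 2
FML033 II.3 0 0 1 1
FML034 II.1 0 0 1 2
FML034 II.2 0 0 2 2
FML034 II.3 0 0 1 1
FML035 II.1 0 0 1 2
FML035 II.2 0 0 2 2
FML035 II.3 0 0 1 1
FML036 II.1 0 0 1 2
FML036 II.2 0 0 2 2
FML036 II.3 0 0 1 1
FML037 II.1 0 0 1 2
FML037 II.2 0 0 2 2
FML037 II.3 0 0 1 1
FML038 II.1 0 0 1 2
FML038 II.2 0 0 2 2
FML038 II.3 0 0 1 1
FML039 II.1 0 0 1 2
FML039 II.2 0 0 2 2
FML039 II.3 0 0 1 1
FML040 II.1 0 0 1 2
FML040 II.2 0 0 2 2
FML040 II.3 0 0 1 1
FML041 II.1 0 0 1 2
FML041 II.2 0 0 2 2
FML041 II.3 0 0 1 1
FML042 II.1 0 0 1 2
FML042 II.2 0 0 2 2
FML042 II.3 0 0 1 1
FML043 II.1 0 0 1 2
FML043 II.2 0 0 2 2
FML043 II.3 0 0 1 1
FML044 II.1 0 0 1 2
FML044 II.2 0 0 2 2
FML044 II.3 0 0 1 1
FML045 II.1 0 0 1 2
FML045 II.2 0 0 2 2
FML045 II.3 0 0 1 1
FML046 II.1 0 0 1 2
FML046 II.2 0 0 2 2
FML046 II.3 0 0 1 1
FML047 II.1 0 0 1 2
FML047 II.2 0 0 2 2
FML047 II.3 0 0 1 1
FML048 II.1 0 0 1 2
FML048 II.2 0 0 2 2
FML048 II.3 0 0 1 2
FML048 II.4 0 0 2 1
FML049 II.1 0 0 1 2
FML049 II.2 0 0 2 2
FML049 II.3 0 0 1 1
FML050 II.1 0 0 1 2
FML050 II.2 0 0 2 2
FML050 II.3 0 0 1 1
FML051 II.1 0 0 1 2
FML051 II.2 0 0 2 2
FML051 II.3 0 0 1 1
FML052 II.1 0 0 1 2
FML052 II.2 0 0 2 2
FML052 II.3 0 0 1 1
FML053 II.1 0 0 1 2
FML053 II.2 0 0 2 2
FML053 II.3 0 0 1 1
FML054 II.1 0 0 1 2
FML054 II.2 0 0 2 2
FML054 II.3 0 0 1 1
FML055 II.1 0 0 1 2
FML055 II.2 0 0 2 2
FML055 II.3 0 0 1 1
FML056 II.1 0 0 1 2
FML056 II.2 0 0 2 2
FML056 II.3 0 0 1 1
FML057 II.1 0 0 1 2
FML057 II.2 0 0 2 2
FML057 II.3 0 0 1 1
FML058 II.1 0 0 1 2
FML058 II.2 0 0 2 2
FML058 II.3 0 0 1 1
FML059 II.1 0 0 1 2
FML059 II.2 0 0 2 2
FML059 II.3 0 0 1 1
FML060 II.1 0 0 1 2
FML060 II.2 0 0 2 2
FML060 II.3 0 0 1 1
FML061 II.1 0 0 1 2
FML061 II.2 0 0 2 2
FML061 II.3 0 0 1 1
FML062 II.1 0 0 1 2
FML062 II.2 0 0 2 2
FML062 II.3 0 0 1 1
FML063 II.1 0 0 1 2
FML063 II.2 0 0 2 2
FML063 II.3 0 0 1 2
FML063 II.4 0 0 2 1
FML064 II.1 0 0 1 2
FML064 II.2 0 0 2 2
FML064 II.3 0 0 1 2
FML064 II.4 0 0 2 1
FML065 II.1 0 0 1 2
FML065 II.2 0 0 2 2
FML065 II.3 0 0 1 2
FML065 II.4 0 0 2 1
FML066 II.1 0 0 1 2
FML066 II.2 0 0 2 2
FML066 II.3 0 0 1 2
FML066 II.4 0 0 2 1
FML067 II.1 0 0 1 2
FML067 II.2 0 0 2 2
FML067 II.3 0 0 1 2
FML067 II.4 0 0 2 1
FML068 II.1 0 0 1 2
FML068 II.2 0 0 2 2
FML068 II.3 0 0 1 2
FML068 II.4 0 0 2 1
FML069 II.1 0 0 1 2
FML069 II.2 0 0 2 2
FML069 II.3 0 0 1 2
FML069 II.4 0 0 2 1
FML070 II.1 0 0 1 2
FML070 II.2 0 0 2 2
FML070 II.3 0 0 1 2
FML070 II.4 0 0 2 1
FML071 II.1 0 0 1 2
FML071 II.2 0 0 2 2
FML071 II.3 0 0 1 2
FML071 II.4 0 0 2 1
FML072 II.1 0 0 1 2
FML072 II.2 0 0 2 2
FML072 II.3 0 0 1 2
FML072 II.4 0 0 2 1
FML073 II.1 0 0 1 2
FML073 II.2 0 0 2 2
FML073 II.3 0 0 1 2
FML073 II.4 0 0 2 1
FML074 II.1 0 0 1 2
FML074 II.2 0 0 2 2
FML074 II.3 0 0 1 2
FML074 II.4 0 0 2 1
FML075 II.1 0 0 1 2
FML075 II.2 0 0 2 2
FML075 II.3 0 0 1 2
FML075 II.4 0 0 2 1
FML076 II.1 0 0 1 2
FML076 II.2 0 0 2 2
FML076 II.3 0 0 1 2
FML076 II.4 0 0 2 1
FML077 II.1 0 0 1 2
FML077 II.2 0 0 2 2
FML077 II.3 0 0 1 2
FML077 II.4 0 0 2 1
FML078 II.1 0 0 1 2
FML078 II.2 0 0 2 2
FML078 II.3 0 0 1 2
FML078 II.4 0 0 2 1
FML079 II.1 0 0 1 2
FML079 II.2 0 0 2 2
FML079 II.3 0 0 1 2
FML079 II.4 0 0 2 1
FML080 II.1 0 0 1 2
FML080 II.2 0 0 2 2
FML080 II.3 0 0 1 2
FML080 II.4 0 0 2 1
FML081 II.1 0 0 1 2
FML081 II.2 0 0 2 2
FML081 II.3 0 0 1 2
FML081 II.4 0 0 2 1
FML082 II.1 0 0 1 2
FML082 II.2 0 0 2 2
FML082 II.3 0 0 1 2
FML082 II.4 0 0 2 1
FML083 II.1 0 0 1 2
FML083 II.2 0 0 2 2
FML083 II.3 0 0 1 2
FML084 II.1 0 0 1 2
FML084 II.2 0 0 2 2
FML084 II.3 0 0 1 2
FML085 II.1 0 0 1 2
FML085 II.2 0 0 2 2
FML085 II.3 0 0 1 2
FML086 II.1 0 0 1 2
FML086 II.2 0 0 2 2
FML086 II.3 0 0 1 2
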