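b012 b023
b046 b048
b003 b045
b030 b049
b001 b022
b007 b047
b001 b011
b007 b027
b014 b025
b002 b004
b019 b049
b031 b046
b023 b042
b016 b048
b033 b035
b013 b032
b033 b034
b011 b013
b008 b022
b031 b033
b018 b032
b002 b048
b003 b019
b026 b036
b024 b031
b024 b044
b023 b043
b010 b042
b006 b046
b004 b039
b031 b049
b004 b009
b006 b026
b024 b029
b015 b030
b024 b047
b020 b047
b033 b048
b011 b024
b043 b047
b018 b040
b029 b035
b017 b028
b039 b043
b013 b029
b024 b038
b005 b023
b014 b045
b007 b045
b002 b008
b014 b038
b015 b041
b025 b026
b003 b008
b017 b035
b002 b035
b007 b039
b013 b016
b042 b043
b040 b041
b023 b025
b003 b043
b013 b042
b007 b024
b010 b038
b022 b046
b003 b044
b002 b021
b027 b048
b003 b024
b008 b016
b032 b033
b003 b048
b019 b028
b013 b048
b001 b028
b017 b021
b012 b020
b029 b033
b003 b029
b001 b002
b019 b022
b039 b049
b025 b037
b013 b026
b035 b042
b026 b037
b006 b014
b030 b039
b008 b047
b027 b031
b017 b020
b014 b048
b044 b045
b014 b030
b017 b036
b020 b022
b026 b047
b002 b003
b009 b011
b020 b045
b013 b034
b019 b029
b002 b013
b001 b035
b013 b041
b015 b049
b001 b047
b037 b040
b014 b047
b004 b010
b016 b037
b021 b046
b011 b043
b004 b031
b005 b025
b028 b046
b012 b015
b007 b031
b019 b025
b002 b027
b022 b025
b008 b036
b010 b020
b010 b030
b008 b021
b013 b028
b020 b035
b010 b018
b027 b029
b007 b032
b024 b049
b018 b020
b029 b039
b010 b031
b017 b034
b035 b046
b037 b049
b036 b043
b010 b034
b010 b027
b009 b010
b019 b036
b017 b022
b002 b030
b029 b032
b014 b032
b023 b039
b005 b020
b001 b032
b026 b034
b024 b030
b026 b040
b004 b028
b007 b017
b014 b020
b004 b020
b023 b044
b026 b039
b013 b046
b027 b043
b033 b045
b039 b046
b011 b041
b035 b041
b019 b024
b021 b026
b006 b049
b017 b042
b022 b039
b001 b013
b007 b042
b015 b018
b005 b016
b031 b039
b013 b025
b011 b022
b012 b048
b012 b016
b004 b047
b021 b033
b015 b029
b019 b027
b008 b035
b033 b042
b003 b016
b025 b042
b034 b037
b003 b020
b028 b036
b003 b040
b015 b020
b032 b046
b035 b037
b010 b014
b009 b031
b007 b040
b012 b049
b010 b013
b001 b041
b008 b027
b011 b016
b021 b042
b035 b047
b005 b032
b035 b068
b042 b062
b035 b077
b008 b069
b047 b071
b024 b068
b036 b097
b041 b097
b035 b103
b038 b093
b043 b098
b029 b093
b010 b102
b024 b097
b040 b096
b017 b103
b036 b093
b016 b099
b019 b104
b008 b103
b025 b100
b031 b102
b024 b104
b027 b099
b038 b097
b020 b099
b035 b105
b024 b096
b052 b079
b054 b078
b087 b089
b072 b091
b054 b092
b085 b087
b067 b072
b064 b077
b061 b086
b051 b058
b068 b081
b088 b091
b073 b084
b056 b065
b060 b075
b062 b070
b056 b064
b062 b087
b056 b077
b076 b091
b070 b076
b060 b061
b061 b092
b080 b085
b050 b056
b079 b086
b058 b078
b060 b079
b078 b086
b054 b062
b051 b065
b060 b080
b056 b073
b055 b063
b052 b075
b058 b085
b061 b072
b054 b064
b050 b076
b051 b068
b071 b086
b065 b068
b052 b092
b056 b070
b090 b091
b059 b092
b061 b073
b078 b088
b060 b088
b072 b080
b057 b067
b050 b081
b064 b065
b057 b072
b082 b087
b050 b068
b055 b078
b055 b086
b075 b077
b052 b074
b054 b056
b052 b071
b054 b073
b050 b053
b052 b054
b077 b088
b067 b076
b077 b082
b062 b065
b053 b059
b058 b090
b073 b091
b061 b070
b085 b091
b080 b083
b057 b058
b078 b091
b050 b072
b066 b089
b074 b082
b078 b080
b069 b071
b082 b086
b054 b061
b056 b083
b069 b076
b060 b068
b066 b091
b080 b088
b053 b060
b068 b090
b066 b080
b067 b083
b063 b075
b050 b052
b057 b087
b063 b091
b081 b082
b072 b077
b061 b088
b057 b078
b050 b071
b054 b069
b067 b075
b079 b081
b060 b086
b079 b085
b055 b077
b067 b081
b069 b077
b073 b086
b054 b081
b057 b086
b053 b072
b061 b087
b055 b058
b072 b092
b086 b091
b071 b077
b051 b081
b052 b061
b082 b090
b069 b084
b052 b067
b056 b086
b067 b070
b077 b089
b078 b084
b058 b081
b061 b089
b073 b080
b052 b083
b060 b062
b073 b074
b055 b084
b073 b092
b060 b077
b060 b078
b062 b085
b056 b085
b051 b067
b061 b067
b062 b072
b069 b088
b058 b089
b083 b084
b065 b085
b063 b074
b052 b055
b063 b083
b077 b085
b055 b076
b069 b078
b051 b084
b076 b081
b064 b075
b086 b090
b057 b062
b052 b062
b082 b091
b081 b084
b053 b056
b071 b081
b081 b087
b069 b086
b078 b081
b075 b088
b055 b083
b063 b092
b058 b075
b059 b086
b057 b068
b050 b055
b077 b095
b063 b101
b054 b098
b072 b099
b092 b095
b082 b097
b050 b096
b059 b095
b082 b105
b077 b100
b089 b094
b062 b094
b089 b093
b067 b093
b070 b095
b077 b093
b065 b104
b092 b101
b060 b093
b059 b093
b097 b105
b099 b105
b098 b100
b093 b103
b096 b101
b101 b104
b093 b105
b097 b103
b093 b098
b096 b097
b101 b105
b094 b101
b093 b095
b099 b104
b095 b098
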